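Package: neurofb
Title: Design, Simulation and Analysis of Closed-Loop fMRI Neurofeedback Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for block-design amygdala neurofeedback experiments with
    multi-echo EPI: transition-balanced block schedule generation with
    counterbalanced direction mapping, a streaming feedback engine
    (TE-weighted echo combination, rest-baseline scaling, dot-history frame
    logs), offline GLM analysis with the canonical double-gamma HRF and
    percent-signal-change conversion, heart-rate and
    respiration-volume-per-time extraction from physiological waveforms, and
    group statistics (one-tailed t-tests, bootstrap Cohen's d, 3x2x2
    repeated-measures ANOVA via within-subject contrasts). A synthetic-data
    module generates multi-echo ROI and volume time series with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
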