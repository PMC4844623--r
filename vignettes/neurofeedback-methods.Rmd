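---
title: "Models and methods behind neurofb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurofb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofb)
```

`neurofb` implements a desk-scale model of a closed-loop amygdala
neurofeedback experiment: subjects see their own region-of-interest (ROI)
BOLD signal as moving dots and are asked to push it up or down in
prescribed blocks, without being given any regulation strategy. The package
covers the experiment end to end -- block-design generation, the real-time
feedback signal chain, offline GLM/percent-signal-change analysis,
physiological condition analysis, and group statistics -- driven by a
synthetic-data generator with known ground truth, since no subject scans
are available to ship. This vignette documents the models, the defaults and
their units, the numerical choices, and what the synthetic validation does
and does not establish.

## Block design

A run is a sequence of 12-TR blocks (TR = 2.54 s, so 30.48 s per block) in
three conditions: left-regulation, right-regulation, and rest. Runs start
with a rest block; after it, each condition occurs `n_per_condition` times
(8 in the canonical design). Two constraints define the randomization:
conditions always change between adjacent blocks, and each of the six
ordered transition types (left→right, left→rest, ...) occurs equally often
-- `n_per_condition / 2` times, which is why `n_per_condition` must be
even. `generate_schedule()` samples these sequences by backtracking search
with transition-count bookkeeping and uniform tie-breaking among feasible
continuations; the constraints themselves say nothing about *how* to
sample, so this sampler is a package choice. A counting argument fixes the
last block: rest occurs `n + 1` times but has only `n` out-transitions
available, so every valid schedule ends on rest. `validate_schedule()`
checks all invariants and reports rather than raises.

Run timing follows directly: a continuous-feedback (CF) run is
25 × 12 × 2.54 s = 762 s (12:42 min). In end-of-block feedback (EoBF)
runs the dots are hidden during regulation and shown for a 2-TR window
after each block. Whether those windows replace or extend the 12
regulation TRs is ambiguous in the protocol description; `neurofb` appends
them after every block including the initial rest, because only that
choice reproduces the printed 14:49 run length
(25 × 14 × 2.54 s = 889 s).

### Direction counterbalancing

Whether "left" means up- or down-regulation is balanced across subjects,
which cancels any feedback-independent left/right bias in the group
UP−DOWN contrast. The protocol says only that roughly half the subjects
got each assignment; `assign_direction_mapping()` makes this deterministic
by alternating on the enrollment index, so any even cohort is split
exactly in half. The screen convention (another undocumented detail) is
fixed and tested: positive displayed values move dots right, and the
mapping's `sign` is the factor applied to the scaled signal, so
`sign = +1` exactly when left means down.

## Real-time feedback chain

Each volume of the multi-echo acquisition (six echoes, TE = 8.6--57 ms)
yields one ROI value: echoes are combined with fixed weights
$w_n \propto TE_n e^{-TE_n/T_2^*}$, normalized to maximum 1, with
$T_2^* = 30$ ms assumed for the amygdala. For the six protocol echo times
this reproduces the published weights 0.59, 0.90, 1, 0.97, 0.88, 0.77.
The package uses a weighted *average* (divide by $\sum w_n$) rather than a
weighted sum so the combined signal stays on the scale of the input
echoes; the feedback display is scale-free either way.

Display scaling is anchored per run: the mean and sample SD
(`n−1`; the population/sample choice is undocumented upstream and is a
stated package decision) of the combined signal over volumes 6--15 define
the baseline. The signal maps to screen position as
$(\text{value}-\mu_b)/(4\sigma_b)$, clipped to $[-1, 1]$: the mean sits at
screen center and a 4-SD offset at the edge. Scaling state is local to a
run -- nothing carries across runs -- which implements the per-run scaling
reset against scanner drift.

One caveat the package documents rather than hides: with 12-TR blocks the
initial rest block spans volumes 1--12, so baseline volumes 13--15
nominally belong to the second block. The window is nevertheless the one
the original pipeline used (it is defensible through the roughly 2-TR
hemodynamic delay, during which the measured signal still reflects rest),
and `estimate_baseline()` implements it verbatim; tests assert the window
size and placement, not a containment that cannot hold.

Frames before volume 16 carry raw values only and are flagged
pre-baseline; what was displayed during this period is unspecified
upstream, so the engine emits no display positions for it. The dot
history keeps the 12 most recent displayed values. In EoBF mode every
frame is still computed and only the display windows are marked visible,
so frame logs are uniform across feedback types; clipping at the screen
edge (rather than rescaling) is assumed.

## Offline GLM and percent signal change

The run-level model regresses the combined ROI series on UP and DOWN
boxcars convolved with the canonical double-gamma HRF (response delay
6 s, undershoot delay 16 s, dispersions 1, undershoot ratio 1/6, 32 s
kernel, peak-normalized), built on a microtime grid of 16 bins per TR and
sampled at the first bin of each TR. Rest is the implicit baseline. EoBF
runs get a third regressor over the display windows; regulation boxcars
span the full 12-TR block only (whether display windows were carved out
of the condition regressors upstream is unknown; this is the simpler
reading). Six motion regressors are appended when a motion table is
supplied. High-pass filtering at 1/128 Hz is implemented as
discrete-cosine nuisance regressors -- the projection is equivalent to
pre-filtering and simpler to test; `floor(2 \cdot N \cdot TR / 128)` basis
functions fall below the cutoff (11 for a 300-volume run).

Coefficients convert to percent signal change as
$$\mathrm{PSC} = \frac{\beta \cdot \max(\text{single event} \otimes \mathrm{HRF}) \cdot 100}{\beta_{\text{constant}}},$$
where the "single event" is a one-TR boxcar convolved at the microtime
grid -- a convention inherited from standard analysis software and made
explicit (and configurable) here. With the implicit baseline, the three
contrasts satisfy `up_rest = psc_up`, `rest_down = -psc_down`, and
`up_down = psc_up - psc_down` identically.

## Synthetic data

The generator produces what the analysis consumes, with recorded truth:

* **Multi-echo decay.** Echo $n$ fluctuates around
  $s_0 e^{-TE_n/T_2^*}$; by default $s_0 = 1000$ a.u. and
  $T_2^* = 30$ ms, the value the echo weights assume.
* **BOLD effect.** A fractional modulation common to all echoes,
  constructed from the same HRF convolution the analysis uses and
  normalized by the single-event peak, i.e. expressed directly in PSC
  units: `effect_up = 0.01` is recovered as `psc_up` = 1.0% exactly at
  zero noise. Modeling the effect as a modulation of the combined signal
  (rather than a $T_2^*$ perturbation) is a deliberate simplification
  that makes ground truth unambiguous. Note that a sustained 12-TR block
  plateaus *above* the single-event peak by a known factor (~2.2), so
  amplitudes are "per single-event peak", not plateau heights.
* **Noise and drift.** White noise per echo (default SD 8 a.u., which
  gives the combined ROI signal a temporal SNR near 100 -- a realistic
  value for an amygdala ROI average) and a linear drift (default
  0.05 a.u./volume) that the high-pass basis must absorb. No noise
  magnitudes are documented for the original data; these defaults are
  stated here once and used throughout.
* **Physiology.** Respiration is an amplitude-modulated sinusoid
  (default period 4 s, i.e. 15 breaths/min) plus white noise; the pulse
  is a von-Mises-shaped peaked waveform at 1.1 Hz (66 bpm). Sampling is
  50 Hz (the recorder's rate is not documented). Per-condition
  modulation factors let tests construct condition-locked ventilation
  changes with a known direction.
* **Cohorts.** `make_cohort()` draws per-subject true UP−DOWN PSC
  effects from $N(\text{mean}, \text{SD}^2)$, so the true group Cohen's
  d is mean/SD; the default (0.43, 1.0) mirrors a moderate transfer-run
  effect. Each subject's effect is split symmetrically
  (`effect_up = +e/2`, `effect_down = -e/2`), mappings alternate, and
  every random stage has its own recorded seed.

What the generator does *not* emulate: motion-by-susceptibility
interactions, spikes, nonlinear drift, spatially structured noise,
cardiac/respiratory aliasing into the BOLD series, or any coupling
between physiology and the fMRI signal. Passing tests therefore establish
that the pipeline is *internally* correct and calibrated -- unbiased PSC
recovery, nominal type-I error, honest bootstrap coverage -- not that it
is robust to every artifact of real scanner data.

## Physiological analysis

Heart rate is 60 over the inter-beat interval of detected pulse peaks;
respiration volume per time (RVT) is, per breath, the peak-to-trough
depth divided by the local breath-to-breath period (for a sinusoid of
amplitude $A$ and period $T$, exactly $2A/T$). The exact windowing of the
toolbox the original analysis used is not documented; this per-breath
definition is the package's stated choice. Both series are interpolated
onto TR-bin centers. Peak detection is prominence-based (threshold
0.3 × waveform SD) with a minimum separation of 0.5 × the median
inter-peak interval -- all configurable. QC flags loss of signal
(deviation below 1% of range for over 5 s, or a flat trace) and excessive
plateaus (identical-sample runs over 2 s covering more than 10% of the
trace). Condition means use an optional whole-TR lag shift, default 0 for
physiological series; the relative UP−DOWN difference is normalized by
the REST mean (whether the original measure was normalized or a
percentage is unstated; normalization is the package's reading).

## Group statistics

Per-subject UP−DOWN PSC values feed a one-tailed one-sample t-test
(UP > DOWN) and Cohen's d = mean/SD (sample SD throughout) with a
percentile bootstrap CI over 1000 draws -- percentile, not BCa, since
nothing more specific is documented. The learning-curve analysis is a
3 × 2 × 2 repeated-measures ANOVA (training day × feedback type ×
regulation direction) computed as tests of within-subject contrasts:
normalized polynomial contrasts (linear (−1,0,1), quadratic (1,−2,1))
over training day, difference contrasts over the two-level factors, each
effect a one-sample t on per-subject contrast scores with F = t² on
(1, n−1) df. Contrast tests need no sphericity correction, which is why
this construction was chosen over an omnibus decomposition. Incomplete
subjects are excluded listwise per analysis with the reduced df carried
through. Correlations (Pearson/Spearman) and the Bonferroni-adjusted
alpha (`alpha/m`) round out the toolkit.

## Numerical choices and degenerate inputs

* Microtime resolution: 16 bins per TR; convolution by FFT padded to a
  composite length, verified in tests against a direct-sum oracle.
* Volume indices are 1-based everywhere, including logs, matching the
  "volumes 6--15" convention; all times are in seconds.
* A constant baseline window (SD = 0) is an error -- display scaling is
  undefined, and the engine refuses rather than guesses.
* Rank-deficient designs fail with the collinear columns named; motion
  tables default to absent rather than all-zero columns, which would be
  collinear with nothing and useless.
* PSC conversion errors on a near-zero constant coefficient.
* RM-ANOVA contrast scores with zero variance are reported as F = 0
  (identically zero scores) or F = ∞ (constant nonzero offset) rather
  than failing inside the t-test.
* Flat waveforms yield zero peaks and are flagged unusable downstream,
  never an error mid-pipeline.

## Validation problem sizes

The test suite validates schedule balance over 100 seeds per design
size; PSC recovery over 100 low-noise runs (median absolute error below
10% of a 1% true effect); d-recovery and bootstrap coverage over 200
cohorts of 32 subjects (mean estimated d within ±0.05 of the true 0.43,
CI coverage 90--98%); and type-I error over 500 null cohorts of 32
subjects run through the full simulate-fit-test pipeline (rejection rate
within the binomial band around 5%). These sizes are the package's chosen
trade-off between Monte-Carlo resolution and a test suite that stays
pleasant to run.

## Known limitations

Slice-time correction, motion correction, distortion correction, spatial
normalization, smoothing and whole-brain mapping are out of scope: masks
and motion parameters are inputs, and the volume mode operates on a small
synthetic grid (12 × 12 × 8 voxels, 2-voxel-radius spherical "amygdala")
as a stand-in for a parcellation-derived mask. The physiological module
is descriptive (condition summaries), not corrective (no RETROICOR-style
regressors). The generator's independence of BOLD and physiological
signals means cross-modal confounds -- e.g. respiration driving global
signal -- can be constructed only through the condition-locked modulation
hooks, not emergently.
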