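#' Ground-truth parameters for one synthetic subject
#'
#' Collects everything the generator needs for one subject: the baseline
#' signal and resting T2* of the mono-exponential multi-echo decay, the
#' fractional BOLD amplitudes of the two regulation conditions, noise and
#' drift magnitudes, and the breathing/cardiac parameters. BOLD
#' amplitudes are expressed in the units of the percent-signal-change
#' formula (fraction of baseline at single-event-peak scale), so an
#' `effect_up` of 0.01 is recovered by the analysis as `psc_up` = 1.0%.
#'
#' @param s0 Baseline signal at TE = 0, arbitrary units (> 0).
#' @param t2star_rest_ms Resting T2* in ms (> 0).
#' @param effect_up,effect_down Fractional BOLD amplitude of the UP and
#'   DOWN regulation conditions (unitless; PSC/100).
#' @param noise_sd Per-echo white-noise SD, arbitrary units (>= 0).
#' @param drift_slope Linear drift in a.u. per volume.
#' @param breath_period_s Respiration period in seconds (> 0).
#' @param breath_amp Respiration waveform amplitude, arbitrary units.
#' @param pulse_rate_hz Cardiac rate in Hz.
#' @return An `nf_subject` list.
#' @examples
#' subject_params(effect_up = 0.005, effect_down = -0.005)
#' @export
subject_params <- function(s0 = 1000, t2star_rest_ms = 30,
                           effect_up = 0.002, effect_down = -0.002,
                           noise_sd = 8, drift_slope = 0.05,
                           breath_period_s = 4, breath_amp = 1,
                           pulse_rate_hz = 1.1) {
  if (s0 <= 0) abort("`s0` must be positive.")
  if (t2star_rest_ms <= 0) abort("`t2star_rest_ms` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (breath_period_s <= 0) abort("`breath_period_s` must be positive.")
  structure(
    list(s0 = s0, t2star_rest_ms = t2star_rest_ms,
         effect_up = effect_up, effect_down = effect_down,
         noise_sd = noise_sd, drift_slope = drift_slope,
         breath_period_s = breath_period_s, breath_amp = breath_amp,
         pulse_rate_hz = pulse_rate_hz),
    class = "nf_subject"
  )
}

#' @export
print.nf_subject <- function(x, ...) {
  cat("<nf_subject> s0 =", x$s0, "T2* =", x$t2star_rest_ms,
      "ms; effects", x$effect_up, "/", x$effect_down,
      "; noise_sd =", x$noise_sd, "\n")
  invisible(x)
}

ideal_bold_vec <- function(schedule, effects, acq, hrf) {
  reg <- condition_regressors(schedule, acq, hrf)
  out <- numeric(nrow(reg))
  for (cond in intersect(names(effects), colnames(reg))) {
    out <- out + effects[[cond]] * reg[, cond]
  }
  out / hrf$single_event_peak
}

#' Noise-free fractional BOLD response for a schedule
#'
#' Builds per-condition boxcars, convolves them with the canonical HRF on
#' a fine grid, samples per volume, and sums them weighted by the
#' per-condition amplitudes. The response is normalized by the
#' single-event peak of the HRF, so amplitudes are in the same units the
#' PSC formula reports (an amplitude of 0.01 corresponds to 1% signal
#' change); a sustained 12-TR block plateaus above its amplitude by the
#' known plateau-to-single-event-peak ratio.
#'
#' @param schedule An `nf_schedule`.
#' @param effects Named amplitudes, e.g. `c(UP = 0.01, DOWN = -0.01)`.
#' @param acq An `nf_acq`.
#' @param hrf An `nf_hrf` (default canonical at `tr/16`).
#' @return Tibble `volume`, `bold_frac`.
#' @export
ideal_bold <- function(schedule, effects, acq = acquisition_params(),
                       hrf = NULL) {
  hrf <- hrf %||% canonical_hrf(dt = acq$tr_seconds / 16,
                                tr_seconds = acq$tr_seconds)
  frac <- ideal_bold_vec(schedule, as.list(effects), acq, hrf)
  tibble(volume = seq_along(frac), bold_frac = frac)
}

sphere_mask <- function(grid_dim, radius) {
  center <- (grid_dim + 1) / 2
  idx <- expand.grid(x = seq_len(grid_dim[1]), y = seq_len(grid_dim[2]),
                     z = seq_len(grid_dim[3]))
  d2 <- (idx$x - center[1])^2 + (idx$y - center[2])^2 + (idx$z - center[3])^2
  array(d2 <= radius^2, dim = grid_dim)
}

#' Simulate a multi-echo ROI or volume time series with known ground truth
#'
#' Signal model per echo n: `s0 * exp(-TE_n / T2*) * (1 + bold(t))` plus a
#' linear drift and white noise, where `bold(t)` is the fractional BOLD
#' response of [ideal_bold()] applied identically to all echoes (the BOLD
#' effect is modeled as a fractional modulation of the combined signal, a
#' deliberate simplification that makes percent-signal-change recovery
#' exact at zero noise). Deterministic for a fixed seed.
#'
#' In volume mode a small voxel grid is generated with a spherical
#' "amygdala" mask; in-mask voxels carry the BOLD effect, out-of-mask
#' voxels only baseline, drift and noise (independent per voxel).
#'
#' @param schedule An `nf_schedule` defining the run.
#' @param acq An `nf_acq` (echo times set the decay sampling).
#' @param subject An `nf_subject`.
#' @param seed Integer seed.
#' @param mode `"roi"` (default) or `"volume"`.
#' @param grid_dim Volume-mode grid (default `c(12, 12, 8)`).
#' @param mask_radius Volume-mode mask radius in voxels (default 2).
#' @return ROI mode: an `nf_me_series` tibble (`volume`, `echo`, `te_ms`,
#'   `value`) with attributes `acq`, `subject`, `bold_frac`. Volume mode:
#'   an `nf_me_volumes` list (`data`: one 4D array per echo, `mask`,
#'   `acq`, `subject`, `bold_frac`).
#' @examples
#' sched <- generate_schedule(2, "CF", seed = 1)
#' ser <- simulate_multiecho(sched, acquisition_params(),
#'                           subject_params(noise_sd = 0), seed = 1)
#' @export
simulate_multiecho <- function(schedule, acq, subject, seed = NULL,
                               mode = c("roi", "volume"),
                               grid_dim = c(12, 12, 8), mask_radius = 2) {
  mode <- match.arg(mode)
  n_vol <- sum(schedule$length_trs + schedule$display_trs)
  hrf <- canonical_hrf(dt = acq$tr_seconds / 16, tr_seconds = acq$tr_seconds)
  frac <- ideal_bold_vec(
    schedule, list(UP = subject$effect_up, DOWN = subject$effect_down),
    acq, hrf
  )
  drift <- subject$drift_slope * (seq_len(n_vol) - 1)
  decay <- subject$s0 * exp(-acq$echo_times_ms / subject$t2star_rest_ms)
  gen_roi <- function() {
    map(seq_along(acq$echo_times_ms), function(e) {
      tibble(
        volume = seq_len(n_vol),
        echo = e,
        te_ms = acq$echo_times_ms[e],
        value = decay[e] * (1 + frac) + drift +
          rnorm(n_vol, 0, subject$noise_sd)
      )
    }) |> list_rbind()
  }
  gen_vol <- function(mask) {
    n_vox <- prod(grid_dim)
    in_mask <- as.logical(mask)
    map(seq_along(acq$echo_times_ms), function(e) {
      base <- matrix(rep(decay[e] + drift, each = n_vox), n_vox, n_vol)
      bold <- outer(as.numeric(in_mask), decay[e] * frac)
      noise <- matrix(rnorm(n_vox * n_vol, 0, subject$noise_sd), n_vox, n_vol)
      array(base + bold + noise, dim = c(grid_dim, n_vol))
    })
  }
  if (mode == "roi") {
    out <- if (is.null(seed)) gen_roi() else withr::with_seed(seed, gen_roi())
    out <- new_tibble(out, class = "nf_me_series")
    attr(out, "acq") <- acq
    attr(out, "subject") <- subject
    attr(out, "bold_frac") <- frac
    out
  } else {
    mask <- sphere_mask(grid_dim, mask_radius)
    data <- if (is.null(seed)) gen_vol(mask) else {
      withr::with_seed(seed, gen_vol(mask))
    }
    structure(
      list(data = data, mask = mask, acq = acq, subject = subject,
           bold_frac = frac),
      class = "nf_me_volumes"
    )
  }
}

#' @export
print.nf_me_series <- function(x, ...) {
  cat("<nf_me_series> ", max(x$volume), " volumes x ",
      length(unique(x$echo)), " echoes\n", sep = "")
  NextMethod()
}

#' @export
print.nf_me_volumes <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat("<nf_me_volumes> grid ", paste(d[1:3], collapse = "x"), ", ",
      d[4], " volumes x ", length(x$data), " echoes, mask ",
      sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Simulate respiration and pulse waveforms
#'
#' Respiration is an amplitude-modulated sinusoid plus white noise; the
#' pulse is a periodic peaked waveform (von Mises-shaped) at the cardiac
#' rate. When a schedule is supplied, per-condition modulation factors
#' scale the breathing amplitude block by block, producing
#' condition-locked ventilation changes with known direction.
#'
#' @param subject An `nf_subject` (breathing/cardiac parameters).
#' @param duration_s Run duration in seconds; derived from
#'   `schedule`/`acq` when those are given.
#' @param schedule,acq Optional run timing for condition-locked modulation.
#' @param condition_modulation Optional named factors, e.g.
#'   `c(UP = 1, DOWN = 2, REST = 1)`, applied to the breathing amplitude
#'   during the matching regulation condition.
#' @param fs Sampling rate in Hz (default 50).
#' @param seed Integer seed.
#' @param noise_sd Additive white-noise SD on the respiration trace,
#'   relative to `breath_amp` (default 0.02).
#' @return An `nf_physio` tibble `time_s`, `respiration`, `pulse`, with
#'   attribute `fs`.
#' @export
simulate_physio <- function(subject, duration_s = NULL, schedule = NULL,
                            acq = NULL, condition_modulation = NULL,
                            fs = 50, seed = NULL, noise_sd = 0.02) {
  if (is.null(duration_s)) {
    if (is.null(schedule) || is.null(acq)) {
      abort("Supply `duration_s` or both `schedule` and `acq`.")
    }
    duration_s <- run_duration(schedule, acq)
  }
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  m <- rep(1, length(t))
  if (!is.null(condition_modulation) && !is.null(schedule)) {
    sv <- schedule_volumes(schedule)
    vol_at_t <- pmin(nrow(sv), floor(t / acq$tr_seconds) + 1)
    reg <- sv$regulation[vol_at_t]
    known <- reg %in% names(condition_modulation)
    m[known] <- as.numeric(condition_modulation[reg[known]])
  }
  gen <- function() {
    resp <- subject$breath_amp * m * sin(2 * pi * t / subject$breath_period_s) +
      rnorm(length(t), 0, noise_sd * subject$breath_amp)
    pulse <- exp(8 * (cos(2 * pi * subject$pulse_rate_hz * t) - 1))
    tibble(time_s = t, respiration = resp, pulse = pulse)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- new_tibble(out, class = "nf_physio")
  attr(out, "fs") <- fs
  out
}

#' Simulate a motion-parameter table
#'
#' Zeros by default (motion correction is out of scope for the package);
#' with `amplitude > 0`, slow sinusoidal nuisance columns are generated
#' for regression tests.
#'
#' @param n_volumes Number of volumes.
#' @param amplitude Peak amplitude of the sinusoidal columns (default 0).
#' @param seed Integer seed for random phases.
#' @return Tibble with 6 columns `trans_x..rot_z`, one row per volume.
#' @export
simulate_motion <- function(n_volumes, amplitude = 0, seed = NULL) {
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  gen <- function() {
    v <- seq_len(n_volumes)
    out <- vapply(seq_along(cols), function(i) {
      if (amplitude == 0) rep(0, n_volumes) else {
        amplitude * sin(2 * pi * v / (40 + 15 * i) + stats::runif(1, 0, 2 * pi))
      }
    }, numeric(n_volumes))
    colnames(out) <- cols
    as_tibble(out)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a cohort of synthetic subjects with known group effect
#'
#' Per-subject true UP-DOWN percent-signal-change effects are drawn from
#' a normal distribution with the requested mean and SD, so the true
#' group Cohen's d is `effect_mean / effect_sd`. Each subject gets a
#' deterministic, balanced direction mapping (alternating by enrollment
#' index), an independently generated transition-balanced schedule, and
#' (optionally) a simulated multi-echo ROI run with the subject's effect
#' split symmetrically over UP and DOWN. True effects are recorded
#' alongside the fixtures.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param effect_mean,effect_sd Mean and SD (> 0) of the per-subject true
#'   UP-DOWN PSC effect, in %.
#' @param seed Integer seed for the whole cohort.
#' @param acq An `nf_acq`.
#' @param n_per_condition Blocks per condition (default 8).
#' @param feedback_type Run type for the fixtures (default `"NONE"`, the
#'   transfer run).
#' @param subject Template `nf_subject`; per-subject effects override its
#'   `effect_up`/`effect_down`.
#' @param simulate Generate the per-subject series fixtures (default
#'   TRUE); if FALSE only truth, mappings and seeds are returned.
#' @param include_physio Also simulate physiological waveforms.
#' @return An `nf_cohort` tibble: `subject`, `left_means`,
#'   `true_up_down` (%), per-subject seeds, and list-columns `schedule`,
#'   `series` (and `physio`) when simulated.
#' @examples
#' coh <- make_cohort(4, effect_mean = 0.43, effect_sd = 1, seed = 7)
#' @export
make_cohort <- function(n_subjects, effect_mean = 0.43, effect_sd = 1,
                        seed = NULL, acq = acquisition_params(),
                        n_per_condition = 8, feedback_type = "NONE",
                        subject = subject_params(), simulate = TRUE,
                        include_physio = FALSE) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (effect_sd <= 0) abort("`effect_sd` must be positive.")
  draw <- function() {
    tibble(
      subject = seq_len(n_subjects),
      true_up_down = rnorm(n_subjects, effect_mean, effect_sd),
      schedule_seed = sample.int(.Machine$integer.max, n_subjects),
      series_seed = sample.int(.Machine$integer.max, n_subjects),
      physio_seed = sample.int(.Machine$integer.max, n_subjects)
    )
  }
  base <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  base$left_means <- vapply(base$subject, function(i) {
    assign_direction_mapping(i - 1)$left_means
  }, character(1))
  if (simulate) {
    base$schedule <- map2(base$schedule_seed, base$left_means, function(s, lm) {
      generate_schedule(n_per_condition, feedback_type, seed = s,
                        mapping = direction_mapping(lm))
    })
    base$series <- pmap(base[c("schedule", "series_seed", "true_up_down")],
      function(schedule, series_seed, true_up_down) {
        subj <- subject
        subj$effect_up <- true_up_down / 200
        subj$effect_down <- -true_up_down / 200
        simulate_multiecho(schedule, acq, subj, seed = series_seed)
      })
    if (include_physio) {
      base$physio <- map2(base$schedule, base$physio_seed, function(sch, s) {
        simulate_physio(subject, schedule = sch, acq = acq, seed = s)
      })
    }
  }
  out <- new_tibble(base[c("subject", "left_means", "true_up_down",
                           "schedule_seed", "series_seed", "physio_seed",
                           intersect(c("schedule", "series", "physio"),
                                     names(base)))],
                    class = "nf_cohort")
  attr(out, "acq") <- acq
  attr(out, "effect_mean") <- effect_mean
  attr(out, "effect_sd") <- effect_sd
  out
}
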