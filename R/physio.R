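#' Detect peaks in a sampled physiological waveform
#'
#' Two-pass detection: local maxima are screened by topographic
#' prominence (at least `prominence_factor` times the waveform SD), then
#' thinned so no two peaks are closer than `min_distance_factor` times
#' the median inter-peak interval, keeping the higher peak of any
#' conflicting pair. A flat waveform yields zero peaks.
#'
#' @param waveform Numeric sampled trace.
#' @param fs Sampling rate in Hz (> 0).
#' @param prominence_factor Prominence threshold as a multiple of the
#'   waveform SD (default 0.3).
#' @param min_distance_factor Minimum peak separation as a multiple of
#'   the median inter-peak interval (default 0.5).
#' @return Peak times in seconds (possibly empty).
#' @examples
#' t <- seq(0, 10, by = 1 / 50)
#' detect_peaks(sin(2 * pi * t), 50)  # ~0.25, 1.25, ...
#' @export
detect_peaks <- function(waveform, fs, prominence_factor = 0.3,
                         min_distance_factor = 0.5) {
  if (fs <= 0) abort("`fs` must be positive.")
  w <- as.numeric(waveform)
  n <- length(w)
  if (n < 3 || sd(w) == 0) return(numeric(0))
  cand <- which(w[2:(n - 1)] > w[1:(n - 2)] & w[2:(n - 1)] >= w[3:n]) + 1L
  if (length(cand) == 0) return(numeric(0))
  prom <- vapply(cand, function(i) {
    v <- w[i]
    lmin <- v
    j <- i - 1L
    while (j >= 1L && w[j] <= v) {
      if (w[j] < lmin) lmin <- w[j]
      j <- j - 1L
    }
    if (j < 1L) lmin <- min(w[1:i])
    rmin <- v
    j <- i + 1L
    while (j <= n && w[j] <= v) {
      if (w[j] < rmin) rmin <- w[j]
      j <- j + 1L
    }
    if (j > n) rmin <- min(w[i:n])
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence_factor * sd(w)]
  if (length(keep) < 2) return((keep - 1) / fs)
  min_dist <- min_distance_factor * median(diff(keep))
  accepted <- integer(0)
  for (i in keep[order(w[keep], decreasing = TRUE)]) {
    if (all(abs(accepted - i) >= min_dist)) accepted <- c(accepted, i)
  }
  (sort(accepted) - 1) / fs
}

unusable <- function(tr_grid, reason) {
  structure(rep(NA_real_, length(tr_grid)), usable = FALSE, reason = reason)
}

#' Heart rate per TR bin from pulse peaks
#'
#' Instantaneous rate is 60 over the inter-beat interval, placed at the
#' midpoint of each beat pair and linearly interpolated onto the TR grid
#' (held constant beyond the first/last beat). Rate is invariant to
#' amplitude scaling of the underlying waveform since only peak times
#' enter.
#'
#' @param peaks Peak times in seconds (from [detect_peaks()]).
#' @param tr_grid Times (s) of the TR bins to interpolate onto.
#' @return Numeric heart rate in bpm per TR bin; if fewer than 2 peaks
#'   are available, all-NA with attribute `usable = FALSE`.
#' @export
heart_rate <- function(peaks, tr_grid) {
  if (length(peaks) < 2) return(unusable(tr_grid, "fewer than 2 beats"))
  ibi <- diff(peaks)
  mid <- peaks[-length(peaks)] + ibi / 2
  hr <- 60 / ibi
  if (length(mid) == 1) return(structure(rep(hr, length(tr_grid)), usable = TRUE))
  structure(approx(mid, hr, xout = tr_grid, rule = 2)$y, usable = TRUE)
}

#' Respiration volume per time (RVT) per TR bin
#'
#' Per breath, the peak-to-trough depth is divided by the local
#' breath-to-breath period (central difference of peak times), giving a
#' per-breath ventilation proxy that is interpolated onto the TR grid.
#' For a pure sinusoid of amplitude A and period T this equals 2A/T.
#'
#' @param waveform Respiration trace.
#' @param fs Sampling rate in Hz.
#' @param tr_grid Times (s) of the TR bins.
#' @param ... Passed to [detect_peaks()].
#' @return Numeric RVT (a.u./s) per TR bin; all-NA with
#'   `usable = FALSE` when fewer than 2 breaths are detected.
#' @export
rvt <- function(waveform, fs, tr_grid, ...) {
  peaks <- detect_peaks(waveform, fs, ...)
  troughs <- detect_peaks(-waveform, fs, ...)
  if (length(peaks) < 2 || length(troughs) < 1) {
    return(unusable(tr_grid, "fewer than 2 breaths"))
  }
  w <- as.numeric(waveform)
  peak_val <- w[round(peaks * fs) + 1]
  trough_val <- vapply(peaks, function(p) {
    before <- troughs[troughs < p]
    t0 <- if (length(before)) max(before) else troughs[1]
    w[round(t0 * fs) + 1]
  }, numeric(1))
  k <- length(peaks)
  period <- if (k == 2) rep(diff(peaks), 2) else {
    c(peaks[2] - peaks[1],
      (peaks[3:k] - peaks[1:(k - 2)]) / 2,
      peaks[k] - peaks[k - 1])
  }
  v <- (peak_val - trough_val) / period
  structure(approx(peaks, v, xout = tr_grid, rule = 2)$y, usable = TRUE)
}

#' Quality control of a physiological waveform
#'
#' Flags the two failure modes that make a recording unusable: loss of
#' signal (the trace hugging its mean, or a zero-range trace) and
#' excessive signal plateaus (runs of identical consecutive samples).
#' Reports, never raises; the checks are monotone in the sense that
#' extending a flagged plateau never clears the flag.
#'
#' @param waveform Sampled trace.
#' @param fs Sampling rate in Hz.
#' @param plateau_run_s A run of identical samples longer than this (s)
#'   counts as plateau (default 2).
#' @param plateau_frac Plateau samples above this fraction of the trace
#'   flag it (default 0.1).
#' @param loss_level Deviation from the trace mean below this fraction of
#'   the range counts toward signal loss (default 0.01).
#' @param loss_s Contiguous low-deviation stretch longer than this (s)
#'   flags loss (default 5).
#' @return An `nf_qc` list: `usable` (logical) and `reasons`
#'   (character, empty when usable).
#' @export
qc_waveform <- function(waveform, fs, plateau_run_s = 2, plateau_frac = 0.1,
                        loss_level = 0.01, loss_s = 5) {
  w <- as.numeric(waveform)
  reasons <- character(0)
  rng <- diff(range(w))
  if (rng == 0) {
    reasons <- c(reasons, "loss of signal")
  } else {
    low <- abs(w - mean(w)) < loss_level * rng
    r <- rle(low)
    if (any(r$lengths[r$values] / fs > loss_s)) {
      reasons <- c(reasons, "loss of signal")
    }
    rr <- rle(w)
    plateau_runs <- rr$lengths[rr$lengths / fs > plateau_run_s]
    if (sum(plateau_runs) / length(w) > plateau_frac) {
      reasons <- c(reasons, "excessive signal plateaus")
    }
  }
  structure(list(usable = length(reasons) == 0, reasons = reasons),
            class = "nf_qc")
}

#' @export
print.nf_qc <- function(x, ...) {
  if (x$usable) cat("<nf_qc> usable\n")
  else cat("<nf_qc> flagged:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Derive HR and RVT time courses for one run
#'
#' Runs peak detection, heart-rate and RVT extraction, and waveform QC on
#' a simulated or recorded physio trace, binned to the run's TR grid
#' (bin centers).
#'
#' @param traces An `nf_physio` tibble (`time_s`, `respiration`, `pulse`)
#'   with attribute `fs`, as produced by [simulate_physio()] or
#'   [read_waveform()].
#' @param schedule The run's `nf_schedule`.
#' @param acq An `nf_acq`.
#' @return An `nf_physio_derived` tibble `volume`, `hr_bpm`, `rvt`, with
#'   attributes `qc_pulse`, `qc_resp`, `usable`.
#' @export
derive_physio <- function(traces, schedule, acq) {
  fs <- attr(traces, "fs")
  n_vol <- sum(schedule$length_trs + schedule$display_trs)
  tr_grid <- (seq_len(n_vol) - 0.5) * acq$tr_seconds
  qc_pulse <- qc_waveform(traces$pulse, fs)
  qc_resp <- qc_waveform(traces$respiration, fs)
  hr <- heart_rate(detect_peaks(traces$pulse, fs), tr_grid)
  rv <- rvt(traces$respiration, fs, tr_grid)
  out <- new_tibble(
    tibble(volume = seq_len(n_vol), hr_bpm = as.numeric(hr),
           rvt = as.numeric(rv)),
    class = "nf_physio_derived"
  )
  attr(out, "qc_pulse") <- qc_pulse
  attr(out, "qc_resp") <- qc_resp
  attr(out, "usable") <- qc_pulse$usable && qc_resp$usable &&
    isTRUE(attr(hr, "usable")) && isTRUE(attr(rv, "usable"))
  out
}

#' Per-condition summary of a TR-binned series
#'
#' Means of a per-volume series over the UP, DOWN and REST regulation
#' conditions, plus the relative UP-DOWN difference normalized by the
#' REST mean: `(mean_up - mean_down) / mean_rest`. An optional lag shifts
#' the condition labels later by whole TRs to allow for hemodynamic or
#' physiological delay (default 0 for physiological series). End-of-block
#' display volumes are excluded from all conditions.
#'
#' @param series Numeric series, one value per volume of the schedule.
#' @param schedule An `nf_schedule`.
#' @param lag_trs Non-negative integer label shift (default 0).
#' @return One-row tibble `mean_up`, `mean_down`, `mean_rest`,
#'   `relative_up_down` (NA when the REST mean is 0).
#' @examples
#' sched <- generate_schedule(2, "CF", seed = 1)
#' sv <- schedule_volumes(sched)
#' x <- ifelse(sv$regulation == "UP", 2, 1)
#' condition_summary(x, sched)  # relative_up_down = 1
#' @export
condition_summary <- function(series, schedule, lag_trs = 0) {
  sv <- schedule_volumes(schedule)
  if (length(series) != nrow(sv)) {
    abort("`series` must have one value per schedule volume.")
  }
  reg <- sv$regulation
  reg[sv$phase == "display"] <- NA
  if (lag_trs > 0) reg <- c(rep(NA, lag_trs), head(reg, -lag_trs))
  means <- vapply(c("UP", "DOWN", "REST"), function(cond) {
    idx <- which(!is.na(reg) & reg == cond & !is.na(series))
    if (length(idx) == 0) abort(paste0("No usable volumes in condition ", cond, "."))
    mean(series[idx])
  }, numeric(1))
  rel <- if (means[["REST"]] != 0) {
    (means[["UP"]] - means[["DOWN"]]) / means[["REST"]]
  } else NA_real_
  tibble(mean_up = means[["UP"]], mean_down = means[["DOWN"]],
         mean_rest = means[["REST"]], relative_up_down = rel)
}
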