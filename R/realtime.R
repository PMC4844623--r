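#' Fixed TE-dependent echo-combination weights
#'
#' BOLD sensitivity of a gradient-echo image at echo time TE is
#' proportional to `TE * exp(-TE / T2*)`, so echoes are combined with
#' weights of that form, normalized so the largest weight is 1. For the
#' six echo times 8.6--57 ms and an assumed amygdala T2* of 30 ms this
#' gives 0.59, 0.90, 1, 0.97, 0.88, 0.77 (2 dp). The unnormalized weight
#' is maximal at TE = T2*.
#'
#' @param echo_times_ms Echo times in ms (at least one, positive).
#' @param t2star_ms Assumed tissue T2* in ms (positive).
#' @return Numeric weight vector, same length as `echo_times_ms`,
#'   maximum exactly 1.
#' @examples
#' round(te_weights(c(8.6, 18.3, 28, 38, 48, 57), 30), 2)
#' @export
te_weights <- function(echo_times_ms, t2star_ms) {
  if (length(echo_times_ms) < 1) abort("`echo_times_ms` must not be empty.")
  if (any(echo_times_ms <= 0)) abort("`echo_times_ms` must be positive.")
  if (t2star_ms <= 0) abort("`t2star_ms` must be positive.")
  w <- echo_times_ms * exp(-echo_times_ms / t2star_ms)
  w / max(w)
}

#' Weighted-average combination of multi-echo values
#'
#' Combines per-echo signal values into a single value per volume using a
#' weighted average (`sum(w * v) / sum(w)`), which keeps the combined
#' signal on the scale of the input echoes.
#'
#' @param values Either a numeric vector with one value per echo, or a
#'   matrix with one column per echo (rows are volumes).
#' @param weights Weights from [te_weights()] (one per echo).
#' @return A single combined value, or one per row of `values`.
#' @examples
#' combine_echoes(c(10, 20), c(1, 0.5))  # 40/3
#' @export
combine_echoes <- function(values, weights) {
  if (is.matrix(values)) {
    if (ncol(values) != length(weights)) {
      abort("`values` must have one column per weight.")
    }
    return(as.numeric(values %*% weights) / sum(weights))
  }
  if (length(values) != length(weights)) {
    abort("`values` and `weights` must have equal length.")
  }
  sum(values * weights) / sum(weights)
}

#' Mean signal over a region of interest
#'
#' @param volume Numeric array (any dimensionality) of voxel values.
#' @param mask Logical/0-1 array of the same shape; at least one voxel.
#' @return Arithmetic mean of in-mask voxels.
#' @export
roi_mean <- function(volume, mask) {
  if (!all(dim(volume) == dim(mask) %||% length(mask)) &&
      length(volume) != length(mask)) {
    abort("`volume` and `mask` must have matching shapes.")
  }
  keep <- as.logical(mask)
  if (!any(keep)) abort("`mask` is empty.")
  mean(volume[keep])
}

#' Baseline statistics from the initial rest volumes
#'
#' The display scaling is anchored to the mean and standard deviation of
#' the combined ROI signal over a window of volumes acquired during the
#' initial rest block -- by default volumes 6 to 15 (1-based, inclusive;
#' 10 volumes), which skips the first 5 volumes of T1 saturation. The SD is
#' the sample SD (n - 1).
#'
#' @param series Numeric combined ROI time series (one value per volume).
#' @param window Integer volume indices used (default `6:15`).
#' @return An `nf_baseline`: list with `mean`, `sd`, `window`.
#' @examples
#' b <- estimate_baseline(c(rnorm(5, 100), 1:10 + 100))
#' @export
estimate_baseline <- function(series, window = 6:15) {
  if (length(series) < max(window)) {
    abort("`series` must cover the baseline window.")
  }
  vals <- series[window]
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    abort("Degenerate baseline: constant signal over the window, display scaling undefined.")
  }
  structure(list(mean = mean(vals), sd = s, window = window),
            class = "nf_baseline")
}

#' @export
print.nf_baseline <- function(x, ...) {
  cat("<nf_baseline> mean =", signif(x$mean, 6), "sd =", signif(x$sd, 6),
      "over volumes", min(x$window), "-", max(x$window), "\n")
  invisible(x)
}

#' Scale a signal value to display coordinates
#'
#' A signal equal to the baseline mean maps to 0 (screen center); an
#' offset of 4 baseline SDs maps to +/-1 (screen edge). Values beyond the
#' edge are clipped to the screen.
#'
#' @param value Numeric value(s) of the combined ROI signal.
#' @param baseline An `nf_baseline`.
#' @return Scaled value(s) in `[-1, 1]`.
#' @examples
#' b <- structure(list(mean = 100, sd = 2), class = "nf_baseline")
#' scale_to_display(c(100, 108, 96), b)  # 0, +1, -0.5
#' @export
scale_to_display <- function(value, baseline) {
  if (baseline$sd <= 0) abort("Degenerate baseline (sd <= 0).")
  pmin(1, pmax(-1, (value - baseline$mean) / (4 * baseline$sd)))
}

#' Combine an ROI-mode multi-echo series into one value per volume
#'
#' Applies the fixed TE-dependent weights of [te_weights()] as a weighted
#' average across echoes, volume by volume.
#'
#' @param series An `nf_me_series` tibble (`volume`, `echo`, `value`).
#' @param acq An `nf_acq`; defaults to the series' own attribute.
#' @return Numeric combined series, ordered by volume.
#' @export
combine_me_series <- function(series, acq = NULL) {
  acq <- acq %||% attr(series, "acq")
  if (is.null(acq)) abort("`acq` is required to combine echoes.")
  w <- te_weights(acq$echo_times_ms, acq$t2star_ms)
  n_echo <- length(w)
  vals <- series$value[order(series$echo, series$volume)]
  m <- matrix(vals, ncol = n_echo)
  combine_echoes(m, w)
}

#' Run the streaming feedback engine over a run
#'
#' Replays the real-time signal chain volume by volume: per-echo ROI
#' values are combined with the fixed TE weights, the baseline mean/SD is
#' estimated once the last baseline volume (default volume 15) has
#' arrived, and every subsequent volume is scaled to display coordinates,
#' direction-mapped, and appended to the 12-sample dot history. Scaling
#' state is local to the run: nothing carries over between runs, which is
#' the per-run scaling reset.
#'
#' Volumes up to the end of the baseline window are emitted as
#' pre-baseline frames (raw ROI value only; no display position, since
#' scaling is undefined before the baseline exists). Visibility follows
#' the feedback type: every post-baseline frame for continuous feedback,
#' only the 2-TR end-of-block display windows for EoBF, and none for a
#' transfer run -- the engine computes all frames either way so logs are
#' uniform across feedback types.
#'
#' @param series An `nf_me_series` in ROI mode (tibble with `volume`,
#'   `echo`, `value`), or a numeric vector of already-combined ROI values.
#' @param schedule The run's `nf_schedule` (its mapping and feedback type
#'   drive sign and visibility); may be `NULL` for a bare series, in which
#'   case all frames are treated as continuous feedback.
#' @param acq An `nf_acq` (echo times and T2* for the weights); defaults
#'   to the series' own acquisition attribute.
#' @param mapping Direction mapping; defaults to the schedule's.
#' @param baseline_window Volume indices for [estimate_baseline()].
#' @param history_length Dot-history length (default 12).
#' @return An `nf_frames` tibble: `volume`, `roi_value`, `scaled`,
#'   `displayed`, `visible`, `pre_baseline`, and a list-column `history`
#'   (up to 12 most recent displayed values, oldest first). Attributes:
#'   `baseline`, `mapping`, `feedback_type`.
#' @examples
#' acq <- acquisition_params()
#' sched <- generate_schedule(2, "CF", seed = 1)
#' subj <- subject_params(noise_sd = 0)
#' series <- simulate_multiecho(sched, acq, subj, seed = 2)
#' frames <- run_feedback(series, sched)
#' @export
run_feedback <- function(series, schedule = NULL, acq = NULL, mapping = NULL,
                         baseline_window = 6:15, history_length = 12L) {
  if (inherits(series, "nf_me_series") || (is.data.frame(series) &&
      all(c("volume", "echo", "value") %in% names(series)))) {
    acq <- acq %||% attr(series, "acq")
    vols <- sort(unique(series$volume))
    roi <- combine_me_series(series, acq)
  } else {
    roi <- as.numeric(series)
    vols <- seq_along(roi)
  }
  if (any(vols != seq_along(vols))) {
    abort("Out-of-order or missing volume indices in the series.")
  }
  feedback_type <- if (is.null(schedule)) "CF" else attr(schedule, "feedback_type")
  mapping <- mapping %||%
    (if (!is.null(schedule)) attr(schedule, "mapping")) %||%
    direction_mapping("UP")
  phase <- if (is.null(schedule)) rep("regulation", length(roi)) else {
    sv <- schedule_volumes(schedule)
    if (nrow(sv) != length(roi)) {
      abort("Series length does not match the schedule's volume count.")
    }
    sv$phase
  }
  n <- length(roi)
  pre <- seq_along(roi) <= max(baseline_window)
  baseline <- if (n >= max(baseline_window)) {
    estimate_baseline(roi, baseline_window)
  }
  scaled <- rep(NA_real_, n)
  if (!is.null(baseline)) {
    idx <- which(!pre)
    scaled[idx] <- scale_to_display(roi[idx], baseline)
  }
  displayed <- scaled * mapping$sign
  visible <- switch(feedback_type,
    CF = !pre,
    EoBF = !pre & phase == "display",
    NONE = rep(FALSE, n)
  )
  history <- vector("list", n)
  hist_buf <- numeric(0)
  for (i in seq_len(n)) {
    if (!pre[i]) {
      hist_buf <- c(hist_buf, displayed[i])
      if (length(hist_buf) > history_length) {
        hist_buf <- tail(hist_buf, history_length)
      }
    }
    history[[i]] <- hist_buf
  }
  out <- new_tibble(
    tibble(volume = seq_len(n), roi_value = roi, scaled = scaled,
           displayed = displayed, visible = visible, pre_baseline = pre,
           history = history),
    class = "nf_frames"
  )
  attr(out, "baseline") <- baseline
  attr(out, "mapping") <- mapping
  attr(out, "feedback_type") <- feedback_type
  out
}

#' @export
print.nf_frames <- function(x, ...) {
  b <- attr(x, "baseline")
  cat("<nf_frames> ", nrow(x), " volumes, feedback ",
      attr(x, "feedback_type"), ", baseline mean ",
      if (is.null(b)) "not estimated" else signif(b$mean, 6), "\n", sep = "")
  NextMethod()
}
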