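#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF: a gamma-density response (delay 6 s, dispersion 1)
#' minus a gamma-density undershoot (delay 16 s, dispersion 1) scaled by
#' 1/6, sampled over 32 s and normalized to peak 1. The peak falls near
#' 5 s. `single_event_peak` is the maximum of a one-TR event convolved
#' with the kernel at the same sampling step; it is the scale factor of
#' the percent-signal-change conversion (see [to_psc()]).
#'
#' @param dt Sampling step in seconds (default one sixteenth of the TR).
#' @param tr_seconds Event duration used for `single_event_peak`.
#' @param duration_s Kernel length in seconds (default 32).
#' @return An `nf_hrf`: list with `kernel`, `dt`, `tr_seconds`,
#'   `single_event_peak`.
#' @examples
#' hrf <- canonical_hrf()
#' hrf$dt * (which.max(hrf$kernel) - 1)  # peak time, ~5 s
#' @export
canonical_hrf <- function(dt = 2.54 / 16, tr_seconds = 2.54, duration_s = 32) {
  if (dt <= 0) abort("`dt` must be positive.")
  t <- seq(0, duration_s, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  event <- rep(1, max(1L, round(tr_seconds / dt)))
  structure(
    list(kernel = h, dt = dt, tr_seconds = tr_seconds,
         single_event_peak = max(conv_full(event, h))),
    class = "nf_hrf"
  )
}

# full discrete convolution (length n + k - 1), FFT with padding to a
# composite length for speed
conv_full <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  n_fft <- stats::nextn(n_out, c(2, 3, 5))
  xp <- c(x, numeric(n_fft - length(x)))
  kp <- c(k, numeric(n_fft - length(k)))
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / n_fft
  out[seq_len(n_out)]
}

# Condition regressors sampled per volume: boxcars over the regulation
# (and display) phases on a microtime grid, convolved with the HRF kernel,
# sampled at the first microtime bin of each TR. Returns a matrix with
# columns UP, DOWN and (when present) DISPLAY, in raw convolution units.
condition_regressors <- function(schedule, acq, hrf, microtime = 16L) {
  sv <- schedule_volumes(schedule)
  n_vol <- nrow(sv)
  dt <- acq$tr_seconds / microtime
  kernel <- if (abs(hrf$dt - dt) < 1e-12) hrf$kernel else {
    canonical_hrf(dt = dt, tr_seconds = acq$tr_seconds)$kernel
  }
  cols <- list(
    UP = sv$regulation == "UP" & sv$phase == "regulation",
    DOWN = sv$regulation == "DOWN" & sv$phase == "regulation"
  )
  if (any(sv$phase == "display")) cols$DISPLAY <- sv$phase == "display"
  take <- (seq_len(n_vol) - 1L) * microtime + 1L
  out <- vapply(cols, function(on) {
    fine <- rep(as.numeric(on), each = microtime)
    conv_full(fine, kernel)[take]
  }, numeric(n_vol))
  out
}

#' Number of discrete-cosine high-pass basis functions
#'
#' The slow-drift nuisance space is spanned by DCT basis functions with
#' frequency below the cutoff: `floor(2 * n_volumes * tr * cutoff_hz)`
#' of them (11 for a 300-volume run at TR 2.54 s and 1/128 Hz).
#'
#' @param n_volumes Number of volumes.
#' @param tr_seconds TR in seconds.
#' @param cutoff_hz High-pass cutoff in Hz (default 1/128).
#' @return Integer count.
#' @export
n_hp_basis <- function(n_volumes, tr_seconds, cutoff_hz = 1 / 128) {
  as.integer(floor(2 * n_volumes * tr_seconds * cutoff_hz))
}

hp_basis <- function(n_volumes, tr_seconds, cutoff_hz = 1 / 128) {
  k_max <- n_hp_basis(n_volumes, tr_seconds, cutoff_hz)
  if (k_max == 0L) return(matrix(numeric(0), n_volumes, 0))
  i <- seq_len(n_volumes)
  out <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * (2 * i - 1) / (2 * n_volumes))
  }, numeric(n_volumes))
  colnames(out) <- paste0("hp_cos", seq_len(k_max))
  out
}

#' Build a GLM design matrix for one run
#'
#' Condition boxcars (UP and DOWN regulation; REST is the implicit
#' baseline and never a column) are built on a fine time grid, convolved
#' with the canonical HRF, and sampled once per TR. For end-of-block
#' feedback runs a third regressor covers the 2-TR display windows. Six
#' motion regressors are appended when a motion table is supplied,
#' followed by the discrete-cosine high-pass basis (frequencies below the
#' cutoff, default 1/128 Hz) and a constant column, always last.
#'
#' @param schedule An `nf_schedule`.
#' @param acq An `nf_acq`.
#' @param hrf An `nf_hrf` (default the canonical HRF at `tr/microtime`).
#' @param motion Optional motion-parameter table: data frame or matrix
#'   with exactly 6 columns and one row per volume.
#' @param hp_cutoff_hz High-pass cutoff in Hz; `NULL` disables the basis.
#' @param microtime Fine-grid bins per TR for the convolution (default 16).
#' @return An `nf_design`: numeric matrix with named columns, plus
#'   attributes `condition_cols` and `hrf`.
#' @examples
#' sched <- generate_schedule(2, "CF", seed = 1)
#' X <- build_design(sched, acquisition_params())
#' colnames(X)
#' @export
build_design <- function(schedule, acq, hrf = NULL, motion = NULL,
                         hp_cutoff_hz = 1 / 128, microtime = 16L) {
  hrf <- hrf %||% canonical_hrf(dt = acq$tr_seconds / microtime,
                                tr_seconds = acq$tr_seconds)
  cond <- condition_regressors(schedule, acq, hrf, microtime)
  n_vol <- nrow(cond)
  parts <- list(cond)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) abort("`motion` must have exactly 6 columns.")
    if (nrow(motion) != n_vol) {
      abort("`motion` must have one row per volume of the schedule.")
    }
    colnames(motion) <- paste0("motion", 1:6)
    parts <- c(parts, list(motion))
  }
  if (!is.null(hp_cutoff_hz)) {
    parts <- c(parts, list(hp_basis(n_vol, acq$tr_seconds, hp_cutoff_hz)))
  }
  parts <- c(parts, list(matrix(1, n_vol, 1, dimnames = list(NULL, "constant"))))
  X <- do.call(cbind, parts)
  structure(X, class = c("nf_design", "matrix", "array"),
            condition_cols = intersect(c("UP", "DOWN"), colnames(cond)),
            hrf = hrf)
}

#' Fit the run-level GLM by ordinary least squares
#'
#' @param series Numeric combined ROI time series, one value per design row.
#' @param design An `nf_design` from [build_design()] (or any numeric
#'   matrix with named columns including `constant`).
#' @return An `nf_glm`: list with `betas` (named), `beta_constant`,
#'   `residual_variance`, `fitted`, `residuals`, `df_residual`, and the
#'   design attributes needed downstream.
#' @examples
#' sched <- generate_schedule(2, "CF", seed = 1)
#' acq <- acquisition_params()
#' X <- build_design(sched, acq)
#' y <- as.numeric(X %*% rnorm(ncol(X)))
#' fit <- fit_glm(y, X)
#' @export
fit_glm <- function(series, design) {
  X <- unclass(design)
  y <- as.numeric(series)
  if (length(y) != nrow(X)) {
    abort("`series` length must equal the number of design rows.")
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  betas <- qr.coef(qr_x, y)
  fitted <- as.numeric(X %*% betas)
  res <- y - fitted
  df_res <- length(y) - ncol(X)
  structure(
    list(
      betas = betas,
      beta_constant = unname(betas["constant"]),
      residual_variance = if (df_res > 0) sum(res^2) / df_res else NA_real_,
      fitted = fitted,
      residuals = res,
      df_residual = df_res,
      condition_cols = attr(design, "condition_cols"),
      hrf = attr(design, "hrf"),
      n = length(y)
    ),
    class = "nf_glm"
  )
}

#' @export
print.nf_glm <- function(x, ...) {
  cat("<nf_glm> ", x$n, " volumes, ", length(x$betas), " regressors, ",
      "sigma^2 = ", signif(x$residual_variance, 4), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.nf_glm <- function(x, ...) {
  tibble(term = names(x$betas), estimate = unname(x$betas))
}

#' @export
glance.nf_glm <- function(x, ...) {
  tibble(
    sigma = sqrt(x$residual_variance),
    df.residual = x$df_residual,
    nobs = x$n
  )
}

#' Convert GLM coefficients to percent signal change and contrasts
#'
#' Applies `PSC = beta * max(single event x HRF) * 100 / beta_constant`
#' to each condition regressor, then forms the three contrasts. Because
#' REST is the implicit baseline, `up_rest = psc_up` and
#' `rest_down = -psc_down` hold by construction, and
#' `up_down = psc_up - psc_down`.
#'
#' @param fit An `nf_glm`.
#' @param hrf An `nf_hrf`; defaults to the one stored in the fit.
#' @return An `nf_psc`: one-row tibble with `psc_up`, `psc_down`,
#'   `up_down`, `up_rest`, `rest_down` (all in %).
#' @export
to_psc <- function(fit, hrf = NULL) {
  hrf <- hrf %||% fit$hrf
  if (is.null(hrf)) abort("`hrf` is required (none stored in the fit).")
  if (!all(c("UP", "DOWN") %in% names(fit$betas))) {
    abort("Fit has no UP/DOWN condition regressors.")
  }
  if (!is.finite(fit$beta_constant) || abs(fit$beta_constant) < 1e-10) {
    abort("Near-zero constant-term coefficient: PSC undefined.")
  }
  scale <- hrf$single_event_peak * 100 / fit$beta_constant
  psc_up <- unname(fit$betas["UP"]) * scale
  psc_down <- unname(fit$betas["DOWN"]) * scale
  new_tibble(
    tibble(psc_up = psc_up, psc_down = psc_down,
           up_down = psc_up - psc_down,
           up_rest = psc_up, rest_down = -psc_down),
    class = "nf_psc"
  )
}

#' Mean PSC contrasts over an ROI from a voxelwise volume-mode fit
#'
#' Fits the GLM independently in every in-mask voxel of a volume-mode
#' multi-echo series (echoes combined with the fixed TE weights first),
#' converts each voxel to PSC, and averages the PSC values over the mask.
#'
#' @param volumes An `nf_me_volumes` from
#'   [simulate_multiecho()] with `mode = "volume"` (list with per-echo 4D
#'   arrays, `mask`, `acq`).
#' @param design An `nf_design` for the run.
#' @return An `nf_psc` one-row tibble of mask-averaged values.
#' @export
roi_psc <- function(volumes, design) {
  mask <- as.logical(volumes$mask)
  if (!any(mask)) abort("`mask` is empty.")
  w <- te_weights(volumes$acq$echo_times_ms, volumes$acq$t2star_ms)
  n_vol <- dim(volumes$data[[1]])[4]
  flat <- lapply(volumes$data, function(a) {
    matrix(a, ncol = n_vol)[mask, , drop = FALSE]
  })
  combined <- Reduce(`+`, Map(`*`, flat, w)) / sum(w)
  psc <- lapply(seq_len(nrow(combined)), function(v) {
    to_psc(fit_glm(combined[v, ], design))
  }) |> list_rbind()
  new_tibble(as_tibble(as.list(colMeans(psc))), class = "nf_psc")
}
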