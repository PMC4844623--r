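test_that("canonical HRF has the double-gamma shape", {
  hrf <- canonical_hrf(dt = 0.1)
  expect_equal(hrf$kernel[1], 0)
  expect_equal(max(hrf$kernel), 1)
  peak_t <- (which.max(hrf$kernel) - 1) * hrf$dt
  expect_equal(peak_t, 5, tolerance = 0.11)
  # late undershoot is negative
  expect_lt(min(hrf$kernel), 0)
  expect_gt(hrf$single_event_peak, 0)
  # convolving a unit impulse returns the kernel itself
  imp <- c(1, rep(0, 10))
  expect_equal(conv_oracle(imp, hrf$kernel)[seq_along(hrf$kernel)],
               hrf$kernel)
})

test_that("design matrices carry the expected named columns", {
  acq <- default_acq
  cf <- generate_schedule(2, "CF", seed = 1)
  motion <- simulate_motion(sum(cf$length_trs), amplitude = 0.1, seed = 2)
  X <- build_design(cf, acq, motion = motion)
  expect_equal(colnames(X)[1:2], c("UP", "DOWN"))
  expect_equal(sum(grepl("^motion", colnames(X))), 6)
  expect_equal(colnames(X)[ncol(X)], "constant")
  expect_false("DISPLAY" %in% colnames(X))
  eobf <- generate_schedule(2, "EoBF", seed = 1)
  Xe <- build_design(eobf, acq)
  expect_true("DISPLAY" %in% colnames(Xe))
  expect_error(build_design(cf, acq, motion = motion[, 1:4]), "6 columns")
})

test_that("high-pass basis size follows the DCT counting rule", {
  expect_equal(n_hp_basis(300, 2.54), 11)
  # brute-force oracle: count DCT frequencies below the cutoff
  run_len <- 300 * 2.54
  k <- 1
  while (k / (2 * run_len) < 1 / 128) k <- k + 1
  expect_equal(n_hp_basis(300, 2.54), k - 1)
  sched <- generate_schedule(8, "NONE", seed = 1)
  X <- build_design(sched, default_acq)
  expect_equal(sum(grepl("^hp_cos", colnames(X))), 11)
})

test_that("OLS recovers exact linear combinations and matches normal equations", {
  acq <- default_acq
  sched <- generate_schedule(2, "CF", seed = 4)
  X <- build_design(sched, acq)
  withr::with_seed(5, beta_true <- rnorm(ncol(X)))
  y <- as.numeric(unclass(X) %*% beta_true)
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$betas), beta_true, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
  # normal-equations oracle on random small instances
  withr::with_seed(6, {
    for (rep in 1:50) {
      n <- sample(20:40, 1); p <- sample(3:6, 1)
      Xr <- cbind(matrix(rnorm(n * (p - 1)), n), constant = 1)
      colnames(Xr) <- c(paste0("x", seq_len(p - 1)), "constant")
      yr <- rnorm(n)
      fitr <- fit_glm(yr, Xr)
      oracle <- solve(t(Xr) %*% Xr, t(Xr) %*% yr)
      expect_equal(unname(fitr$betas), as.numeric(oracle), tolerance = 1e-8)
    }
  })
})

test_that("adding a constant shifts only the constant-term coefficient", {
  acq <- default_acq
  sched <- generate_schedule(2, "CF", seed = 4)
  X <- build_design(sched, acq)
  ser <- simulate_multiecho(sched, acq, subject_params(), seed = 7)
  y <- combine_me_series(ser, acq)
  f1 <- fit_glm(y, X)
  f2 <- fit_glm(y + 42, X)
  expect_equal(f2$beta_constant, f1$beta_constant + 42)
  keep <- setdiff(names(f1$betas), "constant")
  expect_equal(f1$betas[keep], f2$betas[keep], tolerance = 1e-10)
})

test_that("rank-deficient designs fail with the collinear column named", {
  X <- cbind(a = rep(1, 10), b = 2 * rep(1, 10), constant = 1)
  expect_error(fit_glm(rnorm(10), X), "collinear")
})

test_that("PSC conversion satisfies the implicit-baseline identities", {
  acq <- default_acq
  sched <- generate_schedule(2, "NONE", seed = 9)
  subj <- subject_params(noise_sd = 0, drift_slope = 0,
                         effect_up = 0.01, effect_down = -0.004)
  ser <- simulate_multiecho(sched, acq, subj, seed = 1)
  X <- build_design(sched, acq)
  psc <- to_psc(fit_glm(combine_me_series(ser, acq), X))
  expect_equal(psc$up_down, psc$psc_up - psc$psc_down)
  expect_equal(psc$up_rest, psc$psc_up)
  expect_equal(psc$rest_down, -psc$psc_down)
  # zero-noise ground truth: 0.01 fractional effect -> 1.0% PSC
  expect_equal(psc$psc_up, 1.0, tolerance = 1e-6)
  expect_equal(psc$psc_down, -0.4, tolerance = 1e-6)
  # a zero coefficient gives zero PSC
  null_ser <- simulate_multiecho(
    sched, acq, subject_params(noise_sd = 0, drift_slope = 0,
                               effect_up = 0, effect_down = 0), seed = 1)
  psc0 <- to_psc(fit_glm(combine_me_series(null_ser, acq), X))
  expect_equal(psc0$psc_up, 0, tolerance = 1e-8)
})

test_that("high-pass basis absorbs drift without touching condition betas", {
  acq <- default_acq
  sched <- generate_schedule(2, "NONE", seed = 10)
  subj <- subject_params(noise_sd = 0.5, drift_slope = 0,
                         effect_up = 0.01, effect_down = -0.01)
  ser <- simulate_multiecho(sched, acq, subj, seed = 2)
  y <- combine_me_series(ser, acq)
  X <- build_design(sched, acq)
  n <- length(y)
  b0 <- fit_glm(y, X)$betas[c("UP", "DOWN")]
  # drift in the filter's passband (independently coded DCT cosines below
  # the cutoff) leaves condition betas untouched
  i <- seq_len(n)
  slow <- 5 + 3 * cos(pi * 1 * (2 * i - 1) / (2 * n)) -
    2 * cos(pi * 2 * (2 * i - 1) / (2 * n))
  b1 <- fit_glm(y + slow, X)$betas[c("UP", "DOWN")]
  expect_equal(b1, b0, tolerance = 1e-6)
  # a linear ramp is not exactly in the cosine span but its leakage into
  # the condition betas is strongly attenuated relative to an unfiltered fit
  ramp <- 0.004 * (i - 1) * acq$tr_seconds
  b_hp <- fit_glm(y + ramp, X)$betas[c("UP", "DOWN")]
  X_nohp <- build_design(sched, acq, hp_cutoff_hz = NULL)
  d_nohp <- fit_glm(y + ramp, X_nohp)$betas[c("UP", "DOWN")] -
    fit_glm(y, X_nohp)$betas[c("UP", "DOWN")]
  expect_lt(max(abs(b_hp - b0)), 0.2 * max(abs(d_nohp)))
})

test_that("UP-DOWN PSC recovery is accurate across low-noise runs", {
  acq <- default_acq
  hrf <- canonical_hrf()
  errs <- vapply(1:100, function(i) {
    sched <- generate_schedule(2, "NONE", seed = i)
    subj <- subject_params(noise_sd = 1, drift_slope = 0,
                           effect_up = 0.005, effect_down = -0.005)
    ser <- simulate_multiecho(sched, acq, subj, seed = i + 500)
    psc <- to_psc(fit_glm(combine_me_series(ser, acq),
                          build_design(sched, acq, hrf = hrf)))
    abs(psc$up_down - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.1)  # < 10% of the true 1% effect
})

test_that("volume-mode ROI PSC matches phantoms and the ROI pipeline", {
  acq <- default_acq
  sched <- generate_schedule(2, "NONE", seed = 12)
  X <- build_design(sched, acq)
  subj <- subject_params(noise_sd = 0, drift_slope = 0,
                         effect_up = 0.01, effect_down = -0.01)
  vols <- simulate_multiecho(sched, acq, subj, seed = 3, mode = "volume")
  rp <- roi_psc(vols, X)
  # uniform-effect phantom: ROI mean equals any single in-mask voxel
  flat <- lapply(vols$data, function(a) matrix(a, ncol = dim(a)[4]))
  w <- te_weights(acq$echo_times_ms, acq$t2star_ms)
  vox <- which(vols$mask)[1]
  single <- combine_echoes(vapply(flat, function(m) m[vox, ],
                                  numeric(ncol(flat[[1]]))), w)
  single_psc <- to_psc(fit_glm(single, X))
  expect_equal(rp$up_down, single_psc$up_down, tolerance = 1e-8)
  # half-effect mask averages to half the PSC
  half <- vols
  idx <- which(half$mask)
  kill <- idx[seq_len(length(idx) %/% 2)]
  n_vol <- dim(half$data[[1]])[4]
  for (e in seq_along(half$data)) {
    m <- matrix(half$data[[e]], ncol = n_vol)
    decay <- subj$s0 * exp(-acq$echo_times_ms[e] / subj$t2star_rest_ms)
    m[kill, ] <- decay  # flatten to baseline
    half$data[[e]] <- array(m, dim = dim(half$data[[e]]))
  }
  rp_half <- roi_psc(half, X)
  expect_equal(rp_half$up_down, rp$up_down / 2, tolerance = 0.05)
  # cross-mode consistency against the ROI pipeline
  ser <- simulate_multiecho(sched, acq, subj, seed = 4)
  roi_mode <- to_psc(fit_glm(combine_me_series(ser, acq), X))
  expect_equal(rp$up_down, roi_mode$up_down, tolerance = 0.02)
})
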