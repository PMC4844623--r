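test_that("TE weighting reproduces the fixed printed weights", {
  w <- te_weights(c(8.6, 18.3, 28, 38, 48, 57), 30)
  expect_equal(round(w, 2), c(0.59, 0.90, 1.00, 0.97, 0.88, 0.77))
  expect_equal(max(w), 1)
  expect_equal(te_weights(30, 30), 1)
  expect_error(te_weights(numeric(0), 30), "empty")
})

test_that("unnormalized TE weight peaks at TE = T2*", {
  # grid-search oracle for TE * exp(-TE/T2*)
  te_grid <- seq(1, 120, by = 0.01)
  expect_equal(te_grid[which.max(te_grid * exp(-te_grid / 30))], 30,
               tolerance = 0.01)
  tes <- c(8.6, 18.3, 28, 38, 48, 57)
  expect_equal(tes[which.max(tes * exp(-tes / 30))], 28)
})

test_that("echo combination is a weighted average", {
  expect_equal(combine_echoes(c(5, 5, 5), c(0.5, 1, 0.7)), 5)
  expect_equal(combine_echoes(c(10, 20), c(1, 0.5)), 40 / 3)
  expect_error(combine_echoes(c(1, 2), c(1, 1, 1)), "equal length")
  # combining a pure-decay series gives a constant across volumes
  acq <- default_acq
  sched <- generate_schedule(2, "CF", seed = 1)
  subj <- subject_params(noise_sd = 0, drift_slope = 0, effect_up = 0,
                         effect_down = 0)
  ser <- simulate_multiecho(sched, acq, subj, seed = 1)
  combined <- combine_me_series(ser, acq)
  expect_lt(diff(range(combined)), 1e-9)
})

test_that("ROI mean matches a brute-force voxel loop", {
  expect_equal(roi_mean(array(7, c(3, 3, 2)), array(TRUE, c(3, 3, 2))), 7)
  vol <- array(0, c(2, 2, 1)); vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3
  mask <- array(FALSE, c(2, 2, 1)); mask[1:2, 1, 1] <- TRUE
  expect_equal(roi_mean(vol, mask), 2)
  withr::with_seed(8, {
    v <- array(rnorm(60), c(5, 4, 3))
    m <- array(runif(60) > 0.5, c(5, 4, 3))
  })
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:4) for (k in 1:3) {
    if (m[i, j, k]) { acc <- acc + v[i, j, k]; cnt <- cnt + 1 }
  }
  expect_equal(roi_mean(v, m), acc / cnt)
  expect_error(roi_mean(v, array(FALSE, c(5, 4, 3))), "empty")
})

test_that("baseline uses sample statistics over a 10-volume window", {
  series <- c(rep(0, 5), 1:10, rep(99, 5))
  b <- estimate_baseline(series)
  expect_equal(b$mean, 5.5)
  expect_equal(b$sd, sd(1:10))
  expect_equal(b$sd, 3.0277, tolerance = 1e-4)
  expect_length(b$window, 10)
  expect_equal(b$window, 6:15)
  expect_error(estimate_baseline(rep(1, 20)), "Degenerate")
  expect_error(estimate_baseline(1:10), "window")
})

test_that("display scaling maps mean to center and 4 SD to the clipped edge", {
  b <- estimate_baseline(c(rep(0, 5), 1:10))
  expect_equal(scale_to_display(b$mean, b), 0)
  expect_equal(scale_to_display(b$mean + 4 * b$sd, b), 1)
  expect_equal(scale_to_display(b$mean - 2 * b$sd, b), -0.5)
  expect_equal(scale_to_display(b$mean + 10 * b$sd, b), 1)   # clipped
  expect_equal(scale_to_display(b$mean - 10 * b$sd, b), -1)
})

test_that("frame history holds the last 12 displayed values", {
  withr::with_seed(2, series <- 100 + rnorm(40, 0, 3))
  fr <- run_feedback(series)
  expect_true(all(fr$pre_baseline[1:15]))
  expect_true(all(is.na(fr$displayed[1:15])))
  # 13th post-baseline frame (volume 28): oldest sample dropped
  expect_length(fr$history[[27]], 12)
  expect_length(fr$history[[28]], 12)
  expect_equal(fr$history[[28]], fr$displayed[17:28])
  expect_false(fr$displayed[16] %in% fr$history[[28]])
  # history is oldest -> newest and ends with the current frame
  expect_equal(tail(fr$history[[30]], 1), fr$displayed[30])
})

test_that("engine replay is bit-stable and per-run independent", {
  acq <- default_acq
  sched <- generate_schedule(2, "EoBF", seed = 5)
  ser <- simulate_multiecho(sched, acq, subject_params(), seed = 6)
  a <- run_feedback(ser, sched)
  other <- simulate_multiecho(sched, acq, subject_params(), seed = 99)
  invisible(run_feedback(other, sched))  # unrelated run in between
  b <- run_feedback(ser, sched)
  expect_identical(a, b)
})

test_that("EoBF visibility is restricted to the display windows", {
  acq <- default_acq
  sched <- generate_schedule(2, "EoBF", seed = 5)
  ser <- simulate_multiecho(sched, acq, subject_params(), seed = 6)
  fr <- run_feedback(ser, sched)
  sv <- schedule_volumes(sched)
  expect_true(all(sv$phase[fr$visible] == "display"))
  expect_false(any(fr$visible & fr$pre_baseline))
  # transfer run shows nothing but still computes every frame
  st <- generate_schedule(2, "NONE", seed = 5)
  st_ser <- simulate_multiecho(st, acq, subject_params(), seed = 6)
  ft <- run_feedback(st_ser, st)
  expect_false(any(ft$visible))
  expect_true(all(!is.na(ft$scaled[!ft$pre_baseline])))
})

test_that("scaling is invariant to affine rescaling of the raw signal", {
  withr::with_seed(3, series <- 500 + rnorm(60, 0, 4))
  a <- run_feedback(series)
  b <- run_feedback(3.7 * series + 123)
  expect_equal(a$scaled, b$scaled, tolerance = 1e-12)
})

test_that("mapping flip negates displayed values but not the ROI signal", {
  acq <- default_acq
  sched <- generate_schedule(2, "CF", seed = 8)
  ser <- simulate_multiecho(sched, acq, subject_params(), seed = 9)
  a <- run_feedback(ser, sched)
  b <- run_feedback(ser, sched,
                    mapping = flip_mapping(attr(sched, "mapping")))
  expect_equal(b$displayed, -a$displayed)
  expect_equal(b$roi_value, a$roi_value)
  expect_equal(b$scaled, a$scaled)
})

test_that("zero-noise displayed plateaus order as the true effects (un-mapped)", {
  acq <- default_acq
  subj <- subject_params(noise_sd = 0.5, drift_slope = 0,
                         effect_up = 0.02, effect_down = -0.02)
  for (lm in c("UP", "DOWN")) {
    sched <- generate_schedule(2, "CF", seed = 11,
                               mapping = direction_mapping(lm))
    ser <- simulate_multiecho(sched, acq, subj, seed = 12)
    fr <- run_feedback(ser, sched)
    sv <- schedule_volumes(sched)
    sign <- attr(sched, "mapping")$sign
    unmapped <- fr$displayed / sign  # back to signal units
    late <- !fr$pre_baseline & sv$volume %% 12 > 6  # plateau part of blocks
    up_mean <- mean(unmapped[late & sv$regulation == "UP"])
    down_mean <- mean(unmapped[late & sv$regulation == "DOWN"])
    expect_gt(up_mean, down_mean)
  }
})

test_that("out-of-order volume indices are rejected", {
  ser <- simulate_multiecho(generate_schedule(2, "CF", seed = 1),
                            default_acq, subject_params(), seed = 1)
  ser$volume[ser$volume == 3 & ser$echo == 1] <- 999
  expect_error(run_feedback(ser, generate_schedule(2, "CF", seed = 1)),
               "volume")
})
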