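#' One-sample t-test on a per-subject group vector
#'
#' Thin, tibble-returning wrapper around the classical one-sample t-test.
#' The one-tailed variant tests the upper tail (mean > `mu0`), matching
#' directed group hypotheses such as UP > DOWN.
#'
#' @param x Numeric vector, one value per subject (n >= 2, non-constant).
#' @param tail `"one"` (upper tail) or `"two"`.
#' @param mu0 Null value (default 0).
#' @return One-row tibble `estimate`, `t`, `df`, `p`.
#' @examples
#' t_one_sample(c(1, 2, 3))  # t = 3.46, df = 2
#' @export
t_one_sample <- function(x, tail = c("one", "two"), mu0 = 0) {
  tail <- match.arg(tail)
  if (length(x) < 2) abort("Need at least 2 observations.")
  if (sd(x) == 0) abort("Zero variance: t-test undefined.")
  ht <- t.test(x, mu = mu0,
               alternative = if (tail == "one") "greater" else "two.sided")
  tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
}

#' Cohen's d with percentile bootstrap confidence interval
#'
#' The group effect size is `d = mean(x) / sd(x)` (sample SD, n - 1).
#' The confidence interval is the percentile interval over bootstrap
#' resamples of the subjects (default 1000 draws), deterministic for a
#' fixed seed.
#'
#' @param x Numeric vector, one value per subject (n >= 3, non-constant).
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble `d`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @examples
#' cohens_d_ci(rnorm(32, 0.43, 1), seed = 1)
#' @export
cohens_d_ci <- function(x, n_boot = 1000, seed = NULL, conf = 0.95) {
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (sd(x) == 0) abort("Zero variance: Cohen's d undefined.")
  d <- mean(x) / sd(x)
  boot <- function() {
    vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      s <- sd(xb)
      if (s == 0) mean(xb) * Inf else mean(xb) / s
    }, numeric(1))
  }
  draws <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  alpha <- (1 - conf) / 2
  ci <- quantile(draws, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  tibble(d = d, ci_low = ci[1], ci_high = ci[2],
         n = length(x), n_boot = n_boot)
}

td_contrasts <- list(
  linear = c(-1, 0, 1) / sqrt(2),
  quadratic = c(1, -2, 1) / sqrt(6)
)

#' 3 x 2 x 2 repeated-measures ANOVA via within-subject contrasts
#'
#' Learning-curve analysis over training day (TD, 3 levels), feedback
#' type (CF vs EoBF) and regulation direction (UP vs DOWN). Every effect
#' is computed as a one-sample test on per-subject contrast scores
#' (polynomial contrasts -- normalized linear `(-1, 0, 1)` and quadratic
#' `(1, -2, 1)` -- over TD; difference contrasts over the two-level
#' factors), with `F = t^2` on (1, n - 1) degrees of freedom. This is the
#' "tests of within-subject contrasts" construction, which needs no
#' sphericity correction. Subjects with incomplete cells are excluded
#' listwise with a warning naming them; the reduced degrees of freedom
#' follow from the complete-case count.
#'
#' @param data Tidy tibble with columns `subject`, `td` (1-3),
#'   `feedback` (`"CF"`/`"EoBF"`), `direction` (`"UP"`/`"DOWN"`), and
#'   `value` -- one row per cell (average CF runs upstream).
#' @return An `nf_rm_anova` tibble: `effect`, `td_contrast`, `F`, `df1`,
#'   `df2`, `p` (two-sided), `n`.
#' @export
rm_anova_3x2x2 <- function(data) {
  needed <- c("subject", "td", "feedback", "direction", "value")
  if (!all(needed %in% names(data))) {
    abort(paste0("`data` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (anyDuplicated(data[c("subject", "td", "feedback", "direction")]) > 0) {
    abort("Duplicate cells: average repeated runs per cell upstream.")
  }
  grid <- tidyr::expand_grid(subject = unique(data$subject), td = 1:3,
                             feedback = c("CF", "EoBF"),
                             direction = c("UP", "DOWN"))
  cells <- left_join(grid, data,
                     by = c("subject", "td", "feedback", "direction"))
  incomplete <- cells |>
    group_by(.data$subject) |>
    summarise(bad = any(is.na(.data$value))) |>
    filter(.data$bad)
  if (nrow(incomplete) > 0) {
    warn(paste0("Excluding subjects with incomplete cells: ",
                paste(incomplete$subject, collapse = ", ")))
    cells <- filter(cells, !.data$subject %in% incomplete$subject)
  }
  subjects <- unique(cells$subject)
  n <- length(subjects)
  if (n < 2) abort("Fewer than 2 complete-case subjects.")
  # rows ordered td slowest, feedback, then direction fastest per subject
  cube <- cells
  two_level <- c(1, -1) / sqrt(2)
  coefs <- function(td_c, f_c, d_c) {
    as.numeric(kronecker(td_c, kronecker(f_c, d_c)))
  }
  mean_c <- function(k) rep(1 / k, k)
  specs <- list()
  for (tdname in names(td_contrasts)) {
    specs[[paste0("TD.", tdname)]] <-
      list("TD", tdname, coefs(td_contrasts[[tdname]], mean_c(2), mean_c(2)))
    specs[[paste0("TD:Feedback.", tdname)]] <-
      list("TD:Feedback", tdname, coefs(td_contrasts[[tdname]], two_level, mean_c(2)))
    specs[[paste0("TD:Direction.", tdname)]] <-
      list("TD:Direction", tdname, coefs(td_contrasts[[tdname]], mean_c(2), two_level))
    specs[[paste0("TD:Feedback:Direction.", tdname)]] <-
      list("TD:Feedback:Direction", tdname,
           coefs(td_contrasts[[tdname]], two_level, two_level))
  }
  specs[["Feedback"]] <- list("Feedback", NA_character_,
                              coefs(mean_c(3), two_level, mean_c(2)))
  specs[["Direction"]] <- list("Direction", NA_character_,
                               coefs(mean_c(3), mean_c(2), two_level))
  specs[["Feedback:Direction"]] <- list("Feedback:Direction", NA_character_,
                                        coefs(mean_c(3), two_level, two_level))
  score_mat <- matrix(cube$value, nrow = 12)  # one column per subject
  # scores smaller than rounding error on the cell values count as zero
  tol <- 1e-10 * max(1, max(abs(cells$value)))
  res <- map(specs, function(sp) {
    scores <- as.numeric(sp[[3]] %*% score_mat)
    if (all(abs(scores) < tol)) {
      # contrast identically zero: no effect
      f_val <- 0; p_val <- 1
    } else if (sd(scores) < 1e-10 * max(abs(scores))) {
      # constant nonzero contrast: no between-subject variability around
      # a real offset, F unbounded
      f_val <- Inf; p_val <- 0
    } else {
      tt <- t.test(scores, mu = 0)
      f_val <- unname(tt$statistic)^2
      p_val <- tt$p.value
    }
    tibble(effect = sp[[1]], td_contrast = sp[[2]],
           F = f_val, df1 = 1, df2 = n - 1, p = p_val, n = n)
  }) |> list_rbind()
  order_fx <- c("TD", "Feedback", "Direction", "TD:Feedback", "TD:Direction",
                "Feedback:Direction", "TD:Feedback:Direction")
  res <- arrange(res, match(.data$effect, order_fx))
  new_tibble(res, class = "nf_rm_anova")
}

#' @export
tidy.nf_rm_anova <- function(x, ...) as_tibble(x)

#' Pearson or Spearman correlation with directional p-value
#'
#' @param x,y Paired numeric vectors (n >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @param tail `"two"`, `"greater"` (one-tailed r > 0) or `"less"`.
#' @return One-row tibble `r`, `p`, `n`, `method`.
#' @examples
#' correlate(1:10, (1:10)^3, method = "spearman")
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      tail = c("two", "greater", "less")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  alternative <- switch(tail, two = "two.sided", greater = "greater",
                        less = "less")
  ht <- suppressWarnings(
    cor.test(x, y, method = method, alternative = alternative, exact = FALSE)
  )
  tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x),
         method = method)
}

#' Bonferroni-adjusted per-test alpha
#'
#' @param alpha Family-wise alpha.
#' @param m Number of tests (>= 1).
#' @return `alpha / m` (0.05 over 22 tests gives 0.00227, printed 0.002).
#' @examples
#' round(bonferroni(0.05, 22), 3)
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) abort("`m` must be >= 1.")
  alpha / m
}

#' Per-subject learning slope over the three training sessions
#'
#' Ordinary least-squares slope of each subject's per-session values
#' against session index 1..3. Subjects missing a session are excluded
#' and reported via a warning.
#'
#' @param data Tidy tibble with columns `subject`, `session` (1-3),
#'   `value`.
#' @return Tibble `subject`, `slope` for complete subjects.
#' @examples
#' learning_slope(tibble::tibble(subject = 1, session = 1:3, value = c(1, 2, 3)))
#' @export
learning_slope <- function(data) {
  needed <- c("subject", "session", "value")
  if (!all(needed %in% names(data))) {
    abort(paste0("`data` must have columns ", paste(needed, collapse = ", "), "."))
  }
  by_subj <- data |>
    filter(!is.na(.data$value)) |>
    group_by(.data$subject) |>
    summarise(complete = setequal(.data$session, 1:3),
              slope = if (setequal(.data$session, 1:3)) {
                xs <- .data$session - mean(.data$session)
                sum(xs * .data$value) / sum(xs^2)
              } else NA_real_)
  dropped <- by_subj$subject[!by_subj$complete]
  if (length(dropped) > 0) {
    warn(paste0("Excluding subjects with missing sessions: ",
                paste(dropped, collapse = ", ")))
  }
  by_subj |> filter(.data$complete) |> select("subject", "slope")
}
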