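#' Study configuration for the end-to-end pipeline
#'
#' A flat, serializable description of a simulated study: acquisition
#' timing, design size, cohort effect distribution, subject noise
#' parameters, and explicit seeds for every random stage. Round-trips
#' unchanged through [write_config()]/[read_config()].
#'
#' @param n_subjects Cohort size (default 32).
#' @param effect_mean,effect_sd Group distribution of true UP-DOWN PSC
#'   effects in % (default 0.43 and 1).
#' @param n_per_condition Blocks per condition (default 8).
#' @param feedback_type Run type simulated per subject (default
#'   `"NONE"`, the transfer run).
#' @param tr_seconds,echo_times_ms,t2star_ms Acquisition parameters.
#' @param noise_sd,drift_slope Subject noise parameters (a.u.).
#' @param include_physio Simulate and summarize physiological waveforms.
#' @param cohort_seed,bootstrap_seed Seeds for cohort generation and the
#'   bootstrap CI.
#' @return An `nf_config` list.
#' @examples
#' cfg <- study_config(n_subjects = 4)
#' @export
study_config <- function(n_subjects = 32, effect_mean = 0.43, effect_sd = 1,
                         n_per_condition = 8, feedback_type = "NONE",
                         tr_seconds = 2.54,
                         echo_times_ms = c(8.6, 18.3, 28, 38, 48, 57),
                         t2star_ms = 30, noise_sd = 8, drift_slope = 0.05,
                         include_physio = FALSE,
                         cohort_seed = 1, bootstrap_seed = 2) {
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      effect_mean = as.numeric(effect_mean),
      effect_sd = as.numeric(effect_sd),
      n_per_condition = as.integer(n_per_condition),
      feedback_type = as.character(feedback_type),
      tr_seconds = as.numeric(tr_seconds),
      echo_times_ms = as.numeric(echo_times_ms),
      t2star_ms = as.numeric(t2star_ms),
      noise_sd = as.numeric(noise_sd),
      drift_slope = as.numeric(drift_slope),
      include_physio = isTRUE(include_physio),
      cohort_seed = as.integer(cohort_seed),
      bootstrap_seed = as.integer(bootstrap_seed)
    ),
    class = "nf_config"
  )
}

#' Write / read a study configuration (YAML)
#'
#' @param config An `nf_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

#' Estimate per-subject regulation effects for a simulated cohort
#'
#' For each subject: combine the multi-echo ROI series with the fixed TE
#' weights, build the run's design matrix, fit the GLM, and convert to
#' percent signal change. Estimates land in the same units as the
#' recorded ground truth (`true_up_down`, %).
#'
#' @param cohort An `nf_cohort` from [make_cohort()] with simulated
#'   series.
#' @param acq An `nf_acq` (defaults to the cohort's).
#' @return The cohort tibble with columns `psc_up`, `psc_down`,
#'   `up_down` appended.
#' @examples
#' coh <- make_cohort(4, seed = 1)
#' est <- estimate_cohort(coh)
#' cor(est$true_up_down, est$up_down)
#' @export
estimate_cohort <- function(cohort, acq = NULL) {
  acq <- acq %||% attr(cohort, "acq")
  if (!"series" %in% names(cohort)) {
    abort("Cohort has no simulated series; call make_cohort(simulate = TRUE).")
  }
  hrf <- canonical_hrf(dt = acq$tr_seconds / 16, tr_seconds = acq$tr_seconds)
  psc <- map2(cohort$schedule, cohort$series, function(sched, ser) {
    design <- build_design(sched, acq, hrf = hrf)
    fit <- fit_glm(combine_me_series(ser, acq), design)
    to_psc(fit, hrf)
  }) |> list_rbind()
  out <- cohort
  out$psc_up <- psc$psc_up
  out$psc_down <- psc$psc_down
  out$up_down <- psc$up_down
  out
}

#' Group-level summary of per-subject regulation effects
#'
#' One-tailed one-sample t-test (UP > DOWN) and Cohen's d with a
#' percentile bootstrap confidence interval.
#'
#' @param up_down Per-subject UP-DOWN PSC values (%).
#' @param bootstrap_seed Seed for the bootstrap.
#' @param n_boot Bootstrap draws (default 1000).
#' @return One-row tibble `mean`, `t`, `df`, `p_one_tailed`, `d`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
group_summary <- function(up_down, bootstrap_seed = NULL, n_boot = 1000) {
  tt <- t_one_sample(up_down, tail = "one")
  dd <- cohens_d_ci(up_down, n_boot = n_boot, seed = bootstrap_seed)
  tibble(mean = tt$estimate, t = tt$t, df = tt$df, p_one_tailed = tt$p,
         d = dd$d, ci_low = dd$ci_low, ci_high = dd$ci_high,
         n = length(up_down))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full synthetic study pipeline
#'
#' Generates a cohort (schedules, multi-echo runs, optional physio
#' waveforms), estimates per-subject percent-signal-change effects,
#' computes the group statistics, and (optionally) writes all tabular
#' artifacts to a directory. Deterministic given the configuration's
#' seeds: identical configs produce byte-identical reports.
#'
#' @param config An `nf_config` from [study_config()].
#' @param out_dir Optional output directory for TSV artifacts
#'   (`manifest.tsv` with ground truth, `psc_table.tsv`,
#'   `group_stats.tsv`, `physio_summary.tsv`).
#' @return An `nf_report` list: `config`, `cohort` (per-subject truth and
#'   estimates), `group` (one-row tibble), and `physio_summary` (or
#'   `NULL`).
#' @examples
#' report <- run_pipeline(study_config(n_subjects = 4))
#' report$group
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  acq <- run_stage("acquisition", acquisition_params(
    tr_seconds = config$tr_seconds, echo_times_ms = config$echo_times_ms,
    t2star_ms = config$t2star_ms
  ))
  subject <- run_stage("subject", subject_params(
    noise_sd = config$noise_sd, drift_slope = config$drift_slope
  ))
  cohort <- run_stage("cohort", make_cohort(
    config$n_subjects, config$effect_mean, config$effect_sd,
    seed = config$cohort_seed, acq = acq,
    n_per_condition = config$n_per_condition,
    feedback_type = config$feedback_type, subject = subject,
    include_physio = config$include_physio
  ))
  est <- run_stage("glm", estimate_cohort(cohort, acq))
  group <- run_stage("group", group_summary(est$up_down,
                                            config$bootstrap_seed))
  physio_summary <- NULL
  if (config$include_physio) {
    physio_summary <- run_stage("physio", {
      map2(cohort$physio, cohort$schedule, function(tr, sched) {
        derived <- derive_physio(tr, sched, acq)
        bind_cols(
          condition_summary(derived$hr_bpm, sched) |>
            rename_with(~ paste0("hr_", .x)),
          condition_summary(derived$rvt, sched) |>
            rename_with(~ paste0("rvt_", .x))
        )
      }) |> list_rbind() |> mutate(subject = cohort$subject, .before = 1)
    })
  }
  est_plain <- select(as_tibble(est), -dplyr::any_of(c("schedule", "series",
                                                       "physio")))
  report <- structure(
    list(config = config, cohort = est_plain, group = group,
         physio_summary = physio_summary),
    class = "nf_report"
  )
  if (!is.null(out_dir)) {
    run_stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      tsv_write(select(est_plain, "subject", "left_means", "true_up_down"),
                file.path(out_dir, "manifest.tsv"))
      tsv_write(select(est_plain, "subject", "psc_up", "psc_down", "up_down"),
                file.path(out_dir, "psc_table.tsv"))
      tsv_write(group, file.path(out_dir, "group_stats.tsv"))
      if (!is.null(physio_summary)) {
        tsv_write(physio_summary, file.path(out_dir, "physio_summary.tsv"))
      }
    })
  }
  report
}

#' @export
print.nf_report <- function(x, ...) {
  g <- x$group
  cat("<nf_report> N =", g$n, "subjects\n")
  cat(sprintf("  mean UP-DOWN PSC = %.3f%%, t(%d) = %.2f, one-tailed p = %.4g\n",
              g$mean, g$df, g$t, g$p_one_tailed))
  cat(sprintf("  Cohen's d = %.2f (95%% CI %.2f-%.2f)\n",
              g$d, g$ci_low, g$ci_high))
  invisible(x)
}
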