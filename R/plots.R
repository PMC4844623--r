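#' Plot a block schedule as a timeline
#'
#' @param object An `nf_schedule`.
#' @param acq An `nf_acq` for the time axis (default package protocol).
#' @param ... Unused.
#' @return A ggplot: one rectangle per block, colored by regulation
#'   direction; end-of-block display windows in grey.
#' @export
autoplot.nf_schedule <- function(object, acq = acquisition_params(), ...) {
  ev <- schedule_events(object, acq)
  ev$regulation <- factor(ev$regulation,
                          levels = c("UP", "DOWN", "REST", "DISPLAY"))
  ggplot(ev, aes(xmin = .data$onset_s / 60,
                 xmax = (.data$onset_s + .data$duration_s) / 60,
                 ymin = 0, ymax = 1, fill = .data$regulation)) +
    geom_rect(color = "white", linewidth = 0.2) +
    scale_fill_manual(values = c(UP = "#D55E00", DOWN = "#0072B2",
                                 REST = "#999999", DISPLAY = "#E6E6E6")) +
    labs(x = "time (min)", y = NULL, fill = NULL,
         title = paste0("Block schedule (",
                        attr(object, "feedback_type"), ")")) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid.major.y = element_blank())
}

#' Plot a feedback frame log
#'
#' @param object An `nf_frames` from [run_feedback()].
#' @param ... Unused.
#' @return A ggplot of the displayed dot position per volume; frames
#'   actually shown to the subject are solid, computed-but-hidden frames
#'   hollow, and the pre-baseline period shaded.
#' @export
autoplot.nf_frames <- function(object, ...) {
  df <- as_tibble(object)
  pre_end <- max(c(0, df$volume[df$pre_baseline]))
  ggplot(df, aes(.data$volume, .data$displayed)) +
    annotate("rect", xmin = -Inf, xmax = pre_end, ymin = -Inf, ymax = Inf,
             alpha = 0.1) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    geom_line(na.rm = TRUE, linewidth = 0.3, color = "grey50") +
    geom_point(aes(shape = .data$visible), na.rm = TRUE, size = 1.2) +
    scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    coord_cartesian(ylim = c(-1, 1)) +
    labs(x = "volume", y = "displayed position (screen units)",
         shape = "visible") +
    theme_minimal()
}

#' Plot derived physiological time courses
#'
#' @param object An `nf_physio_derived` from [derive_physio()].
#' @param ... Unused.
#' @return A ggplot with heart rate and RVT per TR bin, faceted.
#' @export
autoplot.nf_physio_derived <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("hr_bpm", "rvt"),
                            names_to = "measure")
  ggplot(df, aes(.data$volume, .data$value)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~measure, ncol = 1, scales = "free_y",
               labeller = as_labeller(c(hr_bpm = "heart rate (bpm)",
                                        rvt = "RVT (a.u./s)"))) +
    labs(x = "volume", y = NULL) +
    theme_minimal()
}

#' Plot estimated against true per-subject regulation effects
#'
#' @param object An `nf_cohort` with estimates from [estimate_cohort()].
#' @param ... Unused.
#' @return A ggplot scatter of estimated vs true UP-DOWN PSC with the
#'   identity line.
#' @export
autoplot.nf_cohort <- function(object, ...) {
  if (!"up_down" %in% names(object)) {
    abort("Cohort has no estimates; run estimate_cohort() first.")
  }
  ggplot(as_tibble(object), aes(.data$true_up_down, .data$up_down)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point() +
    labs(x = "true UP-DOWN PSC (%)", y = "estimated UP-DOWN PSC (%)") +
    theme_minimal()
}

#' Group mean contrasts with standard errors
#'
#' @param psc_table Tibble with per-subject columns `up_down`, `up_rest`,
#'   `rest_down` (e.g. the cohort of [run_pipeline()]'s report).
#' @return A ggplot of the three group-mean contrasts (+/- 1 SEM).
#' @export
plot_group_psc <- function(psc_table) {
  if (!"up_rest" %in% names(psc_table) && "psc_up" %in% names(psc_table)) {
    psc_table <- mutate(psc_table, up_rest = .data$psc_up,
                        rest_down = -.data$psc_down)
  }
  cols <- intersect(c("up_down", "up_rest", "rest_down"), names(psc_table))
  if (length(cols) == 0) abort("No contrast columns found.")
  df <- tidyr::pivot_longer(psc_table[cols], dplyr::all_of(cols),
                            names_to = "contrast") |>
    group_by(.data$contrast) |>
    summarise(mean = mean(.data$value),
              sem = sd(.data$value) / sqrt(dplyr::n()))
  ggplot(df, aes(.data$contrast, .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    labs(x = NULL, y = "PSC contrast (%)") +
    theme_minimal()
}
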