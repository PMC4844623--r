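#' Acquisition parameters for a multi-echo EPI run
#'
#' Bundles the scanner timing parameters the rest of the package needs: the
#' repetition time, the ordered echo times, the assumed tissue T2* used for
#' echo weighting, and (optionally) the number of volumes per run. Defaults
#' are the multi-echo protocol used throughout the package's examples:
#' TR = 2.54 s and six echoes between 8.6 and 57 ms, with an assumed
#' amygdala T2* of 30 ms.
#'
#' @param tr_seconds Repetition time in seconds. Must be positive.
#' @param echo_times_ms Ordered echo times in milliseconds, strictly
#'   increasing and positive.
#' @param t2star_ms Assumed tissue T2* in milliseconds used for the fixed
#'   echo-combination weights. Must be positive.
#' @param volumes_per_run Optional number of volumes per run.
#'
#' @return An object of class `nf_acq`: a named list with the four fields.
#' @examples
#' acq <- acquisition_params()
#' acq$tr_seconds
#' @export
acquisition_params <- function(tr_seconds = 2.54,
                               echo_times_ms = c(8.6, 18.3, 28, 38, 48, 57),
                               t2star_ms = 30,
                               volumes_per_run = NULL) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort("`tr_seconds` must be a single positive number.")
  }
  if (length(echo_times_ms) < 1 || any(echo_times_ms <= 0) ||
      is.unsorted(echo_times_ms, strictly = TRUE)) {
    abort("`echo_times_ms` must be positive and strictly increasing.")
  }
  if (!is.numeric(t2star_ms) || length(t2star_ms) != 1 || t2star_ms <= 0) {
    abort("`t2star_ms` must be a single positive number.")
  }
  structure(
    list(
      tr_seconds = tr_seconds,
      echo_times_ms = as.numeric(echo_times_ms),
      t2star_ms = t2star_ms,
      volumes_per_run = volumes_per_run
    ),
    class = "nf_acq"
  )
}

#' @export
print.nf_acq <- function(x, ...) {
  cat("<nf_acq> TR =", x$tr_seconds, "s; TE =",
      paste(x$echo_times_ms, collapse = ", "), "ms; T2* =",
      x$t2star_ms, "ms\n")
  invisible(x)
}

schedule_conditions <- c("LEFT", "RIGHT", "REST")

#' Direction mapping between screen side and regulation direction
#'
#' The feedback display moves dots left or right; whether "left" means
#' up- or down-regulation of the target region is counterbalanced across
#' subjects so that any feedback-independent left/right bias cancels at the
#' group level. The package's screen convention is that a positive displayed
#' value moves the dots to the right; `sign` is the factor applied to the
#' scaled signal before display, so `sign = +1` exactly when left means
#' down-regulation (an up-regulated, positive signal then moves right).
#'
#' @param left_means Either `"UP"` or `"DOWN"`: the regulation direction
#'   instructed by a leftward target.
#' @return An object of class `nf_mapping`: list with `left_means` and
#'   `sign` (+1 or -1).
#' @seealso [assign_direction_mapping()], [flip_mapping()]
#' @examples
#' direction_mapping("UP")$sign
#' @export
direction_mapping <- function(left_means = c("UP", "DOWN")) {
  left_means <- match.arg(left_means)
  structure(
    list(left_means = left_means, sign = if (left_means == "DOWN") 1 else -1),
    class = "nf_mapping"
  )
}

#' @export
print.nf_mapping <- function(x, ...) {
  cat("<nf_mapping> LEFT =", x$left_means, "(display sign", x$sign, ")\n")
  invisible(x)
}

#' Deterministic, balanced mapping assignment by enrollment index
#'
#' Alternates the left/up assignment across consecutively enrolled subjects,
#' so any even-sized cohort is split exactly in half between the two
#' mappings.
#'
#' @param subject_index Zero-based enrollment index (>= 0).
#' @return An `nf_mapping`.
#' @examples
#' table(vapply(0:31, function(i) assign_direction_mapping(i)$left_means, ""))
#' @export
assign_direction_mapping <- function(subject_index) {
  if (subject_index < 0 || subject_index != round(subject_index)) {
    abort("`subject_index` must be a non-negative integer.")
  }
  direction_mapping(if (subject_index %% 2 == 0) "UP" else "DOWN")
}

#' Flip a direction mapping
#'
#' @param mapping An `nf_mapping`.
#' @return The opposite `nf_mapping`; flipping twice returns the original.
#' @export
flip_mapping <- function(mapping) {
  direction_mapping(if (mapping$left_means == "UP") "DOWN" else "UP")
}

#' Regulation direction of each schedule condition under a mapping
#'
#' @param condition Character vector of conditions (`LEFT`, `RIGHT`, `REST`).
#' @param mapping An `nf_mapping`.
#' @return Character vector of `UP`, `DOWN`, `REST`.
#' @export
regulation_of <- function(condition, mapping) {
  other <- if (mapping$left_means == "UP") "DOWN" else "UP"
  dplyr::case_match(condition,
    "LEFT" ~ mapping$left_means,
    "RIGHT" ~ other,
    "REST" ~ "REST"
  )
}

new_schedule <- function(blocks, feedback_type, mapping, n_per_condition) {
  out <- new_tibble(blocks, class = "nf_schedule")
  attr(out, "feedback_type") <- feedback_type
  attr(out, "mapping") <- mapping
  attr(out, "n_per_condition") <- n_per_condition
  out
}

#' @export
print.nf_schedule <- function(x, ...) {
  cat("<nf_schedule> ", nrow(x), " blocks, feedback ",
      attr(x, "feedback_type"), ", LEFT = ",
      attr(x, "mapping")$left_means, "\n", sep = "")
  NextMethod()
}

# Backtracking sampler over condition sequences. Bookkeeping: remaining
# occurrences per condition and remaining budget per ordered transition
# type; candidates at each step are shuffled uniformly and dead ends
# backtrack. A node cap bounds each attempt.
sample_condition_sequence <- function(n_per_condition, max_nodes = 250000L) {
  n_blocks <- 3L * n_per_condition + 1L
  remaining <- c(LEFT = n_per_condition, RIGHT = n_per_condition,
                 REST = n_per_condition)
  budget <- matrix(n_per_condition %/% 2L, 3, 3,
                   dimnames = list(schedule_conditions, schedule_conditions))
  diag(budget) <- 0L
  seq_out <- character(n_blocks)
  seq_out[1] <- "REST"
  nodes <- 0L

  recurse <- function(pos) {
    if (pos > n_blocks) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(NA)
    prev <- seq_out[pos - 1L]
    cands <- schedule_conditions[schedule_conditions != prev]
    cands <- cands[remaining[cands] > 0L & budget[prev, cands] > 0L]
    if (length(cands) == 0L) return(FALSE)
    for (cond in sample(cands, length(cands))) {
      remaining[cond] <<- remaining[cond] - 1L
      budget[prev, cond] <<- budget[prev, cond] - 1L
      seq_out[pos] <<- cond
      res <- recurse(pos + 1L)
      if (isTRUE(res) || is.na(res)) return(res)
      remaining[cond] <<- remaining[cond] + 1L
      budget[prev, cond] <<- budget[prev, cond] + 1L
    }
    FALSE
  }

  if (n_per_condition == 0L) return("REST")
  res <- recurse(2L)
  if (isTRUE(res)) seq_out else NULL
}

#' Generate a transition-balanced pseudo-random block schedule
#'
#' Produces an ordered sequence of `LEFT`, `RIGHT` and `REST` blocks that
#' starts with a rest block, never repeats a condition in consecutive
#' blocks, contains each non-initial condition exactly `n_per_condition`
#' times, and -- for even `n_per_condition` -- contains each of the six
#' ordered transition types (e.g. left-regulation followed by rest) exactly
#' `n_per_condition / 2` times. With `n_per_condition = 8` this yields the
#' canonical 25-block run in which every transition type occurs four times.
#' Sampling is a backtracking search with uniform tie-breaking among
#' feasible continuations, so all constraint-satisfying sequences are
#' reachable; it is deterministic for a fixed `seed`.
#'
#' @param n_per_condition Number of blocks per condition after the initial
#'   rest block. Must be even (transition balance needs `3 n` divisible
#'   by 6) and non-negative.
#' @param feedback_type `"CF"` (continuous feedback), `"EoBF"` (end-of-block
#'   feedback: a 2-TR display window appended after every block, including
#'   the initial rest), or `"NONE"` (transfer run, no feedback).
#' @param seed Integer seed; the search is reproducible given the seed.
#' @param mapping Direction mapping attached to the schedule
#'   (see [direction_mapping()]).
#' @param block_length_trs Regulation block length in TRs (default 12).
#' @param max_retries Bounded number of restarts before an explicit error.
#' @return An `nf_schedule`: a tibble with columns `block`, `condition`,
#'   `length_trs`, `display_trs`, plus attributes `feedback_type`,
#'   `mapping`, `n_per_condition`.
#' @examples
#' sched <- generate_schedule(8, "CF", seed = 1)
#' nrow(sched)                       # 25 blocks
#' validate_schedule(sched)$violations
#' @export
generate_schedule <- function(n_per_condition, feedback_type = c("CF", "EoBF", "NONE"),
                              seed = NULL,
                              mapping = direction_mapping("UP"),
                              block_length_trs = 12L,
                              max_retries = 20L) {
  feedback_type <- match.arg(feedback_type)
  if (n_per_condition < 0 || n_per_condition != round(n_per_condition)) {
    abort("`n_per_condition` must be a non-negative integer.")
  }
  if (n_per_condition %% 2 != 0) {
    abort(paste0(
      "`n_per_condition` must be even: with ", n_per_condition,
      " blocks per condition the six ordered transition types cannot all ",
      "occur equally often."
    ))
  }
  draw <- function() {
    for (i in seq_len(max_retries)) {
      s <- sample_condition_sequence(n_per_condition)
      if (!is.null(s)) return(s)
    }
    abort("Schedule search failed after bounded retries.")
  }
  conds <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  display <- if (feedback_type == "EoBF") 2L else 0L
  blocks <- tibble(
    block = seq_along(conds),
    condition = conds,
    length_trs = as.integer(block_length_trs),
    display_trs = display
  )
  new_schedule(blocks, feedback_type, mapping, as.integer(n_per_condition))
}

#' Validate a block schedule against its design constraints
#'
#' Reports, never raises: counts every ordered transition type and each
#' condition, and lists violated constraints (initial rest block, no
#' condition repeats, equal block lengths, balanced condition counts,
#' balanced transition counts for even designs).
#'
#' @param schedule An `nf_schedule` (or any tibble with `condition` and
#'   `length_trs` columns).
#' @return A list of class `nf_validation`: `transition_counts` (tibble
#'   `from`, `to`, `count` over the six ordered types), `condition_counts`,
#'   and a character vector `violations` (empty iff all invariants hold).
#' @export
validate_schedule <- function(schedule) {
  conds <- schedule$condition
  violations <- character()
  if (length(conds) == 0) {
    violations <- c(violations, "empty schedule")
  } else if (conds[1] != "REST") {
    violations <- c(violations, "first block not REST")
  }
  if (any(conds[-1] == conds[-length(conds)])) {
    violations <- c(violations, "condition repeat")
  }
  if (length(unique(schedule$length_trs)) > 1) {
    violations <- c(violations, "unequal block lengths")
  }
  pairs <- expand.grid(from = schedule_conditions, to = schedule_conditions,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  trans <- tibble(from = head(conds, -1), to = tail(conds, -1))
  transition_counts <- as_tibble(pairs) |>
    left_join(count(trans, .data$from, .data$to, name = "count"),
              by = c("from", "to")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$from, .data$to)
  condition_counts <- tibble(condition = schedule_conditions) |>
    left_join(count(tibble(condition = conds), .data$condition, name = "count"),
              by = "condition") |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  # non-initial occurrences must be equal across conditions
  non_initial <- condition_counts$count
  names(non_initial) <- condition_counts$condition
  if (length(conds) > 0 && conds[1] == "REST") {
    non_initial["REST"] <- non_initial["REST"] - 1L
  }
  n <- attr(schedule, "n_per_condition") %||% max(non_initial)
  if (length(conds) > 1 && length(unique(non_initial)) > 1) {
    violations <- c(violations, "unbalanced condition counts")
  }
  if (n %% 2 == 0 && n > 0 &&
      any(transition_counts$count != n %/% 2)) {
    violations <- c(violations, "unbalanced transition counts")
  }
  structure(
    list(transition_counts = transition_counts,
         condition_counts = condition_counts,
         violations = violations),
    class = "nf_validation"
  )
}

#' @export
print.nf_validation <- function(x, ...) {
  if (length(x$violations) == 0) {
    cat("<nf_validation> schedule valid\n")
  } else {
    cat("<nf_validation> violations:", paste(x$violations, collapse = "; "), "\n")
  }
  print(x$transition_counts)
  invisible(x)
}

#' Total duration of a run in seconds
#'
#' Each block contributes its regulation TRs plus any end-of-block display
#' TRs. The canonical 8-blocks-per-condition design gives 762 s (12:42) for
#' continuous feedback and 889 s (14:49) with end-of-block feedback.
#'
#' @param schedule An `nf_schedule`.
#' @param acq An `nf_acq`.
#' @return Duration in seconds.
#' @examples
#' run_duration(generate_schedule(8, "CF", seed = 1), acquisition_params())
#' @export
run_duration <- function(schedule, acq) {
  sum(schedule$length_trs + schedule$display_trs) * acq$tr_seconds
}

#' Expand a schedule to one row per acquired volume
#'
#' @param schedule An `nf_schedule`.
#' @return Tibble with columns `volume` (1-based), `block`, `condition`,
#'   `regulation` (UP/DOWN/REST under the schedule's mapping), and `phase`
#'   (`"regulation"` or `"display"`).
#' @export
schedule_volumes <- function(schedule) {
  mapping <- attr(schedule, "mapping") %||% direction_mapping("UP")
  total <- schedule$length_trs + schedule$display_trs
  within_block <- sequence(total)
  condition <- rep(schedule$condition, times = total)
  reg_map <- c(LEFT = mapping$left_means,
               RIGHT = if (mapping$left_means == "UP") "DOWN" else "UP",
               REST = "REST")
  tibble(
    volume = seq_len(sum(total)),
    block = rep(schedule$block, times = total),
    condition = condition,
    regulation = unname(reg_map[condition]),
    phase = ifelse(within_block > rep(schedule$length_trs, times = total),
                   "display", "regulation")
  )
}

#' Event table for a schedule (onsets and durations in seconds)
#'
#' One row per block phase; display windows appear as condition
#' `"DISPLAY"`. This is the table serialized by [write_schedule()].
#'
#' @param schedule An `nf_schedule`.
#' @param acq An `nf_acq`.
#' @return Tibble `onset_s`, `duration_s`, `condition`, `regulation`.
#' @export
schedule_events <- function(schedule, acq) {
  mapping <- attr(schedule, "mapping") %||% direction_mapping("UP")
  tr <- acq$tr_seconds
  rows <- list()
  onset <- 0
  for (i in seq_len(nrow(schedule))) {
    rows[[length(rows) + 1]] <- tibble(
      onset_s = onset,
      duration_s = schedule$length_trs[i] * tr,
      condition = schedule$condition[i],
      regulation = regulation_of(schedule$condition[i], mapping)
    )
    onset <- onset + schedule$length_trs[i] * tr
    if (schedule$display_trs[i] > 0) {
      rows[[length(rows) + 1]] <- tibble(
        onset_s = onset,
        duration_s = schedule$display_trs[i] * tr,
        condition = "DISPLAY",
        regulation = "DISPLAY"
      )
      onset <- onset + schedule$display_trs[i] * tr
    }
  }
  list_rbind(rows)
}
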