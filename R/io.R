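#' Read and write tabular artifacts as TSV
#'
#' All tabular outputs of the package (schedules, motion tables, frame
#' logs, per-run results) are tab-separated text with a header row; times
#' are in seconds and volume indices 1-based.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `tsv_read()` returns a tibble; `tsv_write()` returns `x`
#'   invisibly.
#' @export
tsv_write <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname tsv_write
#' @export
tsv_read <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

#' Serialize a block schedule to TSV
#'
#' Writes the event table (`onset_s`, `duration_s`, `condition`,
#' `regulation`) preceded by comment-line metadata (`feedback_type`,
#' `left_means`, `tr_seconds`, `n_per_condition`) so the schedule
#' round-trips exactly through [read_schedule()].
#'
#' @param schedule An `nf_schedule`.
#' @param path File path.
#' @param acq An `nf_acq` (TR for onsets).
#' @export
write_schedule <- function(schedule, path, acq) {
  mapping <- attr(schedule, "mapping") %||% direction_mapping("UP")
  meta <- c(
    paste0("# feedback_type: ", attr(schedule, "feedback_type")),
    paste0("# left_means: ", mapping$left_means),
    paste0("# tr_seconds: ", format(acq$tr_seconds, digits = 15)),
    paste0("# n_per_condition: ", attr(schedule, "n_per_condition"))
  )
  writeLines(meta, path)
  readr::write_tsv(schedule_events(schedule, acq), path, append = TRUE,
                   col_names = TRUE)
  invisible(schedule)
}

#' Read a block schedule written by [write_schedule()]
#'
#' @param path File path.
#' @return An `nf_schedule`; block boundaries are reconstructed exactly
#'   from the onsets and durations.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
    if (length(hit) == 0) abort(paste0("Missing schedule metadata: ", key))
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  feedback_type <- get_meta("feedback_type")
  mapping <- direction_mapping(get_meta("left_means"))
  tr <- as.numeric(get_meta("tr_seconds"))
  n_per_condition <- as.integer(get_meta("n_per_condition"))
  events <- tsv_read(path)
  blocks <- events[events$condition != "DISPLAY", ]
  display <- events[events$condition == "DISPLAY", ]
  len <- as.integer(round(blocks$duration_s / tr))
  disp <- integer(nrow(blocks))
  if (nrow(display) > 0) {
    # display windows follow their block immediately
    idx <- findInterval(display$onset_s, blocks$onset_s)
    tab <- table(idx)
    disp[as.integer(names(tab))] <-
      as.integer(round(display$duration_s[!duplicated(idx)] / tr))
  }
  new_schedule(
    tibble(block = seq_len(nrow(blocks)), condition = blocks$condition,
           length_trs = len, display_trs = disp),
    feedback_type, mapping, n_per_condition
  )
}

#' Write and read feedback frame logs
#'
#' The frame log mirrors the text-file interface of the real-time chain:
#' one row per volume with the raw ROI value, scaled and displayed
#' positions, and visibility flag. Reading validates that volume indices
#' are 1-based and contiguous.
#'
#' @param frames An `nf_frames`.
#' @param path File path.
#' @export
write_frames <- function(frames, path) {
  tsv_write(
    tibble(volume_index = frames$volume, roi_value = frames$roi_value,
           scaled = frames$scaled, displayed = frames$displayed,
           visible = frames$visible, pre_baseline = frames$pre_baseline),
    path
  )
  invisible(frames)
}

#' @rdname write_frames
#' @return `read_frames()` returns the frame-log tibble.
#' @export
read_frames <- function(path) {
  log <- tsv_read(path)
  expected <- seq_len(nrow(log))
  bad <- which(log$volume_index != expected)
  if (length(bad) > 0) {
    abort(paste0("Frame log has a volume_index gap at row ", bad[1],
                 " (found ", log$volume_index[bad[1]], ", expected ",
                 expected[bad[1]], ")."))
  }
  log
}

#' Write and read sampled physiological waveforms
#'
#' Single-column text files: a one-line header `fs <rate>` followed by
#' one sample per line.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param path File path.
#' @export
write_waveform <- function(x, fs, path) {
  writeLines(c(paste("fs", format(fs, digits = 15)),
               format(as.numeric(x), digits = 15)), path)
  invisible(x)
}

#' @rdname write_waveform
#' @return `read_waveform()` returns the numeric waveform with attribute
#'   `fs`.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("^fs ", lines[1])) {
    abort("Waveform file must start with a header line 'fs <rate>'.")
  }
  fs <- as.numeric(sub("^fs ", "", lines[1]))
  vals <- as.numeric(lines[-1])
  if (anyNA(vals)) abort("Non-numeric sample in waveform file.")
  structure(vals, fs = fs)
}

#' Assemble physio traces from waveform files
#'
#' @param respiration_path,pulse_path Waveform files written by
#'   [write_waveform()] (equal sampling rates).
#' @return An `nf_physio` tibble.
#' @export
physio_from_files <- function(respiration_path, pulse_path) {
  resp <- read_waveform(respiration_path)
  pulse <- read_waveform(pulse_path)
  if (attr(resp, "fs") != attr(pulse, "fs")) {
    abort("Respiration and pulse sampling rates differ.")
  }
  if (length(resp) != length(pulse)) {
    abort("Respiration and pulse traces have different lengths.")
  }
  fs <- attr(resp, "fs")
  out <- new_tibble(
    tibble(time_s = (seq_along(resp) - 1) / fs,
           respiration = as.numeric(resp), pulse = as.numeric(pulse)),
    class = "nf_physio"
  )
  attr(out, "fs") <- fs
  out
}

#' Write and read an ROI-mode multi-echo series as TSV
#'
#' @param series An `nf_me_series`.
#' @param path File path.
#' @export
write_me_series <- function(series, path) {
  tsv_write(as_tibble(series)[c("volume", "echo", "te_ms", "value")], path)
  invisible(series)
}

#' @rdname write_me_series
#' @param acq An `nf_acq` reattached on read.
#' @export
read_me_series <- function(path, acq) {
  out <- new_tibble(tsv_read(path), class = "nf_me_series")
  attr(out, "acq") <- acq
  out
}

#' Write a volume-mode multi-echo series and mask as NIfTI
#'
#' One 4D NIfTI file per echo (`<prefix>_echo<k>.nii`) plus a binary mask
#' (`<prefix>_mask.nii`).
#'
#' @param volumes An `nf_me_volumes`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_me_volumes <- function(volumes, dir, prefix = "run") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (e in seq_along(volumes$data)) {
    p <- file.path(dir, sprintf("%s_echo%d.nii", prefix, e))
    RNifti::writeNifti(RNifti::asNifti(volumes$data[[e]]), p)
    paths <- c(paths, p)
  }
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(volumes$mask),
                                           dim = dim(volumes$mask))),
                     mask_path)
  invisible(c(paths, mask_path))
}

#' Read a volume-mode multi-echo series from NIfTI files
#'
#' @param echo_paths One 4D NIfTI per echo, in echo order.
#' @param mask_path Binary ROI mask NIfTI.
#' @param acq An `nf_acq` (must list one echo time per file).
#' @return An `nf_me_volumes`.
#' @export
read_me_volumes <- function(echo_paths, mask_path, acq) {
  if (length(echo_paths) != length(acq$echo_times_ms)) {
    abort("Number of echo files must match `acq$echo_times_ms`.")
  }
  data <- lapply(echo_paths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim = dim(a))
  })
  m <- RNifti::readNifti(mask_path)
  structure(
    list(data = data, mask = array(as.numeric(m) > 0, dim = dim(m)),
         acq = acq),
    class = "nf_me_volumes"
  )
}
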