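#' Construct a tri-axial acceleration signal
#'
#' An `accel_signal` is a tibble with columns `time_s`, `x_g`, `y_g`, `z_g`
#' (time in seconds, acceleration in units of standard gravity g) plus
#' attributes `fs` (sampling rate, Hz), `subject_id` and `recording_id`.
#' Sample times must be strictly increasing and uniformly spaced to within
#' 1% relative jitter.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param x_g,y_g,z_g Acceleration channels in g, same length as `time_s`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred as `1 / median(diff(time_s))`
#'   (a single sample defaults to 30 Hz). If given and it disagrees with the
#'   timestamps by more than 1%, a warning is raised and the override wins.
#' @param subject_id,recording_id Opaque string labels.
#' @return An `accel_signal` tibble.
#' @export
#' @examples
#' s <- accel_signal(time_s = (0:59) / 30, x_g = rnorm(60, sd = 0.05),
#'                   y_g = rnorm(60, sd = 0.05), z_g = 1 + rnorm(60, sd = 0.05))
#' signal_fs(s)
accel_signal <- function(time_s, x_g, y_g, z_g, fs = NULL,
                         subject_id = NA_character_,
                         recording_id = NA_character_) {
  n <- length(time_s)
  if (n < 1L) {
    abort("An acceleration signal needs at least one sample.",
          class = "rehabrec_data_error")
  }
  if (length(x_g) != n || length(y_g) != n || length(z_g) != n) {
    abort("time_s, x_g, y_g and z_g must have the same length.",
          class = "rehabrec_data_error")
  }
  if (anyNA(time_s) || anyNA(x_g) || anyNA(y_g) || anyNA(z_g)) {
    abort("Acceleration signals must not contain missing values.",
          class = "rehabrec_data_error")
  }
  dt <- diff(time_s)
  if (n > 1L && any(dt <= 0)) {
    abort("Sample times must be strictly increasing.",
          class = "rehabrec_data_error")
  }
  fs_inferred <- if (n > 1L) 1 / median(dt) else NA_real_
  if (n > 2L) {
    jitter <- max(abs(dt - 1 / fs_inferred)) * fs_inferred
    if (jitter > 0.01) {
      abort(sprintf(
        "Sample spacing is not uniform (relative jitter %.3f > 0.01).", jitter
      ), class = "rehabrec_data_error")
    }
  }
  if (is.null(fs)) {
    fs <- if (is.na(fs_inferred)) 30 else fs_inferred
  } else {
    stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
    if (!is.na(fs_inferred) && abs(fs - fs_inferred) / fs_inferred > 0.01) {
      warn(sprintf(
        "Supplied fs = %g Hz differs from the timestamp-implied %g Hz by > 1%%; using the override.",
        fs, fs_inferred
      ))
    }
  }
  out <- tibble(time_s = as.numeric(time_s), x_g = as.numeric(x_g),
                y_g = as.numeric(y_g), z_g = as.numeric(z_g))
  structure(out,
            fs = as.numeric(fs),
            subject_id = as.character(subject_id),
            recording_id = as.character(recording_id),
            class = c("accel_signal", class(out)))
}

#' Signal attribute accessors
#'
#' @param signal An [accel_signal()].
#' @return `signal_fs()` the sampling rate in Hz; `signal_subject()` and
#'   `signal_recording()` the identifying labels; `n_samples()` the number of
#'   samples.
#' @export
signal_fs <- function(signal) attr(signal, "fs", exact = TRUE) %||% 30

#' @rdname signal_fs
#' @export
signal_subject <- function(signal) attr(signal, "subject_id", exact = TRUE) %||% NA_character_

#' @rdname signal_fs
#' @export
signal_recording <- function(signal) attr(signal, "recording_id", exact = TRUE) %||% NA_character_

#' @rdname signal_fs
#' @export
n_samples <- function(signal) nrow(signal)

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("# accel_signal: %d samples @ %g Hz (%.2f s), subject %s\n",
              nrow(x), signal_fs(x), nrow(x) / signal_fs(x),
              signal_subject(x)))
  NextMethod()
}

rebuild_signal <- function(signal, x_g = NULL, y_g = NULL, z_g = NULL) {
  accel_signal(
    time_s = signal$time_s,
    x_g = x_g %||% signal$x_g,
    y_g = y_g %||% signal$y_g,
    z_g = z_g %||% signal$z_g,
    fs = signal_fs(signal),
    subject_id = signal_subject(signal),
    recording_id = signal_recording(signal)
  )
}

#' Read and write recording CSVs
#'
#' The on-disk recording dialect is a comma-separated UTF-8 file with the
#' mandatory header `time_s,x_g,y_g,z_g`, `.` as decimal separator, one row
#' per sample, values written in 6-decimal fixed notation. The sampling rate
#' is inferred from the timestamps unless `fs` overrides it.
#'
#' @param path File path.
#' @param fs Optional sampling-rate override in Hz (see [accel_signal()]).
#' @param subject_id,recording_id Labels attached to the returned signal.
#' @return `read_recording()` an [accel_signal()]; `write_recording()` the
#'   path, invisibly.
#' @export
read_recording <- function(path, fs = NULL, subject_id = NA_character_,
                           recording_id = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("Recording file does not exist: %s", path),
          class = "rehabrec_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  required <- c("time_s", "x_g", "y_g", "z_g")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Recording %s lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "rehabrec_format_error")
  }
  if (nrow(df) < 1L) {
    abort(sprintf("Recording %s contains no data rows.", path),
          class = "rehabrec_data_error")
  }
  if (is.na(recording_id)) {
    recording_id <- sub("\\.csv$", "", basename(path))
  }
  accel_signal(df$time_s, df$x_g, df$y_g, df$z_g, fs = fs,
               subject_id = subject_id, recording_id = recording_id)
}

#' @rdname read_recording
#' @param signal An [accel_signal()] to write.
#' @export
write_recording <- function(signal, path) {
  stopifnot(inherits(signal, "accel_signal"))
  vals <- as.matrix(signal[, c("time_s", "x_g", "y_g", "z_g")])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Refusing to write a recording containing NA or non-finite values.",
          class = "rehabrec_data_error")
  }
  lines <- c(
    "time_s,x_g,y_g,z_g",
    sprintf("%.6f,%.6f,%.6f,%.6f",
            signal$time_s, signal$x_g, signal$y_g, signal$z_g)
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort(sprintf("Cannot write recording to %s", path),
          class = "rehabrec_io_error")
  }
  invisible(path)
}

#' Read and write annotation CSVs
#'
#' Annotations mark labeled repetition boundaries. The on-disk dialect has
#' the header `subject_id,activity,start_sample,end_sample` with 0-based,
#' half-open sample intervals (`start_sample` inclusive, `end_sample`
#' exclusive), optionally preceded by a `recording` column tying each row to
#' a recording file. In memory, segments use R's 1-based inclusive
#' convention: columns `start` and `end` with length `end - start + 1`;
#' the two conventions denote the same samples (`start = start_sample + 1`,
#' `end = end_sample`).
#'
#' @param path File path.
#' @param allow_unlabeled Accept `"?"` activity codes (emitted for detected
#'   but not-yet-labeled segments)?
#' @return `read_annotations()` a tibble with columns `recording`,
#'   `subject_id`, `activity`, `start`, `end`, sorted by
#'   `(subject_id, recording, start)`; `write_annotations()` the path,
#'   invisibly.
#' @export
read_annotations <- function(path, allow_unlabeled = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file does not exist: %s", path),
          class = "rehabrec_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  required <- c("subject_id", "activity", "start_sample", "end_sample")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Annotation file lacks required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rehabrec_format_error")
  }
  if (!"recording" %in% names(df)) {
    df$recording <- df$subject_id
  }
  ann <- tibble(
    recording = as.character(df$recording),
    subject_id = as.character(df$subject_id),
    activity = as_activity(df$activity, allow_unlabeled = allow_unlabeled),
    start = as.integer(df$start_sample) + 1L,
    end = as.integer(df$end_sample)
  )
  validate_annotations(ann)
  dplyr::arrange(ann, .data$subject_id, .data$recording, .data$start)
}

#' @rdname read_annotations
#' @param annotations Tibble of in-memory annotations (columns `recording`,
#'   `subject_id`, `activity`, `start`, `end`).
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  out <- tibble(
    recording = annotations$recording,
    subject_id = annotations$subject_id,
    activity = as.character(annotations$activity),
    start_sample = as.integer(annotations$start) - 1L,
    end_sample = as.integer(annotations$end)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  required <- c("recording", "subject_id", "activity", "start", "end")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    abort(sprintf("Annotations lack column(s): %s", paste(missing, collapse = ", ")),
          class = "rehabrec_format_error")
  }
  if (any(ann$start < 1L) || any(ann$end < ann$start)) {
    abort("Annotation segments must satisfy 1 <= start <= end.",
          class = "rehabrec_data_error")
  }
  invisible(ann)
}

#' Bundle recordings and annotations into a study
#'
#' A `rehab_study` pairs a named list of recordings with one annotation
#' table, the unit consumed by [loso_cv()], [run_pipeline()] and
#' [compare_segmentation()].
#'
#' @param recordings Named list of [accel_signal()] objects; names must match
#'   the `recording` column of `annotations`.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return A `rehab_study` list with elements `recordings` and `annotations`.
#' @export
rehab_study <- function(recordings, annotations) {
  stopifnot(is.list(recordings), length(recordings) > 0L)
  if (is.null(names(recordings)) || any(names(recordings) == "")) {
    abort("Recordings must be a named list keyed by recording id.",
          class = "rehabrec_data_error")
  }
  validate_annotations(annotations)
  dangling <- setdiff(unique(annotations$recording), names(recordings))
  if (length(dangling) > 0L) {
    abort(sprintf("Annotations reference unknown recording(s): %s",
                  paste(dangling, collapse = ", ")),
          class = "rehabrec_data_error")
  }
  structure(list(recordings = recordings,
                 annotations = dplyr::arrange(annotations, .data$subject_id,
                                              .data$recording, .data$start)),
            class = "rehab_study")
}

#' @export
print.rehab_study <- function(x, ...) {
  cat(sprintf(
    "# rehab_study: %d recordings, %d subjects, %d labeled repetitions\n",
    length(x$recordings), dplyr::n_distinct(x$annotations$subject_id),
    nrow(x$annotations)))
  invisible(x)
}
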