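#' Names of the 24 time-domain features
#'
#' Six statistics (minimum, maximum, range, mean, standard deviation, root
#' mean square) over the four channels `x`, `y`, `z` and the per-sample
#' magnitude `m`, named `<channel>_<stat>` (e.g. `m_rms`). The standard
#' deviation uses the population form `sqrt(mean((a - mean(a))^2))`, which
#' keeps the identity `rms^2 = mean^2 + std^2` exact.
#'
#' @return Character vector of the 24 column names in fixed order.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("x", "y", "z", "m"),
                    c("min", "max", "range", "mean", "std", "rms"),
                    paste, sep = "_")))
}

channel_stats <- function(a) {
  mn <- min(a)
  mx <- max(a)
  mu <- mean(a)
  std <- sqrt(mean((a - mu)^2))
  rms <- sqrt(mean(a^2))
  c(mn, mx, mx - mn, mu, std, rms)
}

# Numeric fast path shared by extract_features() and featurize_dataset().
segment_feature_vector <- function(x, y, z, idx) {
  xx <- x[idx]
  yy <- y[idx]
  zz <- z[idx]
  m <- sqrt(xx^2 + yy^2 + zz^2)
  setNames(c(channel_stats(xx), channel_stats(yy), channel_stats(zz),
             channel_stats(m)), feature_names())
}

#' Extract time-domain features from one segment
#'
#' Computes the 24 statistics of [feature_names()] over the samples
#' `start:end` of a recording: per channel, minimum, maximum, range
#' (`max - min`), mean, population standard deviation and root mean square.
#' The magnitude channel `m = sqrt(x^2 + y^2 + z^2)` is computed per sample
#' before aggregation.
#'
#' @param signal An [accel_signal()] (normally already smoothed with
#'   [moving_average()]).
#' @param start,end Segment bounds, 1-based inclusive, within the recording.
#' @return One-row tibble with the 24 feature columns.
#' @export
#' @examples
#' s <- accel_signal((0:4) / 30, x_g = 1:5, y_g = rep(0, 5), z_g = rep(0, 5))
#' extract_features(s, 1, 5)[, c("x_mean", "x_std", "x_rms")]
extract_features <- function(signal, start, end) {
  stopifnot(inherits(signal, "accel_signal"))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > nrow(signal) ||
      start > end) {
    abort(sprintf(
      "Segment [%s, %s] is empty or outside the recording (1..%d).",
      start, end, nrow(signal)
    ), class = "rehabrec_parameter_error")
  }
  as_tibble(as.list(segment_feature_vector(signal$x_g, signal$y_g,
                                           signal$z_g, start:end)))
}

#' Build a feature table from labeled segments
#'
#' One row per labeled segment: `subject_id`, `recording`, `activity`, then
#' the 24 feature columns. Rows are ordered deterministically by
#' `(subject_id, recording, start)`; duplicate segments yield duplicate rows.
#'
#' @param recordings Named list of [accel_signal()] objects (normally
#'   smoothed), or a [rehab_study()].
#' @param segments Labeled segment tibble (`recording`, `subject_id`,
#'   `activity`, `start`, `end`); defaults to the study's annotations when
#'   `recordings` is a [rehab_study()].
#' @return Feature tibble with `nrow(segments)` rows.
#' @export
featurize_dataset <- function(recordings, segments = NULL) {
  if (inherits(recordings, "rehab_study")) {
    segments <- segments %||% recordings$annotations
    recordings <- recordings$recordings
  }
  validate_annotations(segments)
  empty <- dplyr::bind_cols(
    tibble(subject_id = character(0), recording = character(0),
           activity = as_activity(character(0))),
    as_tibble(setNames(rep(list(numeric(0)), 24L), feature_names())))
  if (nrow(segments) == 0L) return(empty)
  dangling <- setdiff(unique(segments$recording), names(recordings))
  if (length(dangling) > 0L) {
    abort(sprintf("Segments reference unknown recording(s): %s",
                  paste(dangling, collapse = ", ")),
          class = "rehabrec_data_error")
  }
  segments <- dplyr::arrange(segments, .data$subject_id, .data$recording,
                             .data$start)
  feats <- vapply(seq_len(nrow(segments)), function(i) {
    sig <- recordings[[segments$recording[i]]]
    if (segments$end[i] > nrow(sig)) {
      abort(sprintf("Segment [%d, %d] extends past recording %s (%d samples).",
                    segments$start[i], segments$end[i],
                    segments$recording[i], nrow(sig)),
            class = "rehabrec_data_error")
    }
    segment_feature_vector(sig$x_g, sig$y_g, sig$z_g,
                           segments$start[i]:segments$end[i])
  }, numeric(24L))
  dplyr::bind_cols(
    tibble(subject_id = segments$subject_id,
           recording = segments$recording,
           activity = segments$activity),
    as_tibble(t(feats)))
}

#' Read and write feature-table CSVs
#'
#' Dialect: `subject_id`, `recording`, `activity`, then the 24 feature
#' columns of [feature_names()].
#'
#' @param table Feature tibble from [featurize_dataset()].
#' @param path File path.
#' @return `read_features()` the feature tibble; `write_features()` the
#'   path, invisibly.
#' @export
write_features <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(c("subject_id", "activity", feature_names()), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Feature table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rehabrec_format_error")
  }
  df$activity <- as_activity(df$activity)
  as_tibble(df)
}
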