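#' Detection channel for repetition segmentation
#'
#' Builds the one-dimensional channel on which peaks and valleys are
#' detected: the acceleration magnitude, smoothed with a centered
#' (zero-phase) moving mean, with the resting baseline removed. At rest the
#' magnitude of a wrist-worn accelerometer sits at the 1 g gravity level
#' whatever the sensor orientation, so with `baseline = "gravity"`
#' (default) the channel is the absolute deviation `|m - 1|`: rest gaps sit
#' near zero and movement — whether it adds to or opposes gravity — appears
#' as a positive burst. `baseline = "median"` uses the recording's median
#' magnitude as the rest level instead (for data whose calibration offsets
#' the rest level), and `baseline = "none"` returns the smoothed magnitude
#' itself.
#'
#' @param signal An [accel_signal()].
#' @param smooth_length Centered smoothing window in samples (default 10).
#' @param baseline `"gravity"` (`|m - 1|`), `"median"` (`|m - median(m)|`)
#'   or `"none"`.
#' @return Numeric vector, one value per sample.
#' @export
detection_channel <- function(signal, smooth_length = 10L,
                              baseline = c("gravity", "median", "none")) {
  baseline <- match.arg(baseline)
  m <- centered_mean(signal_magnitude(signal), as.integer(smooth_length))
  switch(baseline,
         gravity = abs(m - 1),
         median = abs(m - median(m)),
         none = m)
}

# Local-extremum runs. Returns midpoint index of each run of equal values
# that is strictly higher (maxima) / lower (minima) than both neighbours;
# boundary runs are never extrema (a run touching the signal edge has only
# one neighbour and is excluded, keeping detection deterministic).
local_extrema <- function(v, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") v <- -v
  n <- length(v)
  if (n < 3L) return(integer(0))
  run_start <- which(c(TRUE, v[-1L] != v[-n]))
  run_end <- c(run_start[-1L] - 1L, n)
  k <- length(run_start)
  if (k < 3L) return(integer(0))
  inner <- 2L:(k - 1L)
  is_max <- v[run_start[inner]] > v[run_start[inner] - 1L] &
    v[run_start[inner]] > v[run_end[inner] + 1L]
  idx <- inner[is_max]
  as.integer((run_start[idx] + run_end[idx]) %/% 2L)
}

#' Detect peaks in a detection channel
#'
#' Local maxima with height at least `threshold`, thinned so that any two
#' retained peaks are at least `min_distance` samples apart. Suppression is
#' greedy by descending height (ties broken toward the earlier index), so the
#' output is deterministic: the highest peak is always kept and lower peaks
#' within `min_distance` of a kept peak are dropped.
#'
#' @param channel Numeric vector (see [detection_channel()]).
#' @param threshold Minimum height of a peak, in g.
#' @param min_distance Minimum separation between retained peaks, in samples
#'   (`>= 1`).
#' @return Sorted integer vector of 1-based sample indices.
#' @export
detect_peaks <- function(channel, threshold, min_distance = 1L) {
  if (length(channel) == 0L) {
    abort("Cannot detect peaks in an empty channel.",
          class = "rehabrec_data_error")
  }
  min_distance <- as.integer(min_distance)
  if (is.na(min_distance) || min_distance < 1L) {
    abort("min_distance must be a positive integer.",
          class = "rehabrec_parameter_error")
  }
  cand <- local_extrema(channel, "max")
  cand <- cand[channel[cand] >= threshold]
  if (length(cand) == 0L) return(integer(0))
  ord <- order(-channel[cand], cand)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Detect valleys in a detection channel
#'
#' Local minima with depth at most `threshold` (the highest value a valley
#' may take). All qualifying minima are returned; no distance thinning is
#' applied, since valleys only serve as candidate segment boundaries.
#'
#' @inheritParams detect_peaks
#' @param threshold Highest value of a valley, in g.
#' @return Sorted integer vector of 1-based sample indices.
#' @export
detect_valleys <- function(channel, threshold) {
  if (length(channel) == 0L) {
    abort("Cannot detect valleys in an empty channel.",
          class = "rehabrec_data_error")
  }
  cand <- local_extrema(channel, "min")
  sort(cand[channel[cand] <= threshold])
}

#' Learn segmentation parameters from annotated recordings
#'
#' Derives the dynamic-segmentation thresholds from a labeled training set:
#'
#' * peak threshold `T_p = alpha * min(per-repetition maximum of the
#'   detection channel)` — the minimum value a repetition peak may take,
#'   with a safety margin for unseen subjects;
#' * minimum peak distance `D = floor(beta * min(repetition duration in
#'   samples))`, at least 1;
#' * valley threshold `T_v = gamma * max(per-gap minimum of the detection
#'   channel)`, where gaps are the stretches between consecutive annotated
#'   repetitions of the same recording — the highest value a boundary valley
#'   may take. With no gaps in the training set, `T_v` falls back to
#'   `0.2 * T_p` with a warning.
#'
#' The boundary type is chosen automatically: valley boundaries when the
#' median per-gap minimum is at most `T_v` (rest dips exist between
#' repetitions), peak boundaries otherwise. `T_p > T_v` is enforced;
#' training data violating it raise a degenerate-data error.
#'
#' @param study A [rehab_study()], or a named list of recordings if
#'   `annotations` is given separately.
#' @param annotations Optional annotation tibble (when `study` is a plain
#'   recording list).
#' @param alpha,beta,gamma Safety-margin coefficients (defaults 0.9, 0.8,
#'   1.5).
#' @param boundary_type `"auto"`, `"peak"` or `"valley"`.
#' @param smooth_length,baseline Passed to [detection_channel()].
#' @return A `segmentation_params` object: list with `peak_threshold`,
#'   `min_peak_distance`, `valley_threshold`, `boundary_type` and the
#'   detection-channel settings.
#' @export
learn_segmentation_params <- function(study, annotations = NULL,
                                      alpha = 0.9, beta = 0.8, gamma = 1.5,
                                      boundary_type = c("auto", "peak", "valley"),
                                      smooth_length = 10L,
                                      baseline = c("gravity", "median", "none")) {
  boundary_type <- match.arg(boundary_type)
  baseline <- match.arg(baseline)
  if (inherits(study, "rehab_study")) {
    recordings <- study$recordings
    annotations <- study$annotations
  } else {
    recordings <- study
  }
  if (is.null(annotations) || nrow(annotations) == 0L) {
    abort("Cannot learn segmentation parameters without annotations.",
          class = "rehabrec_data_error")
  }
  validate_annotations(annotations)

  rep_max <- numeric(0)
  durations <- integer(0)
  gap_min <- numeric(0)
  for (rec_id in unique(annotations$recording)) {
    sig <- recordings[[rec_id]]
    if (is.null(sig)) {
      abort(sprintf("Annotations reference unknown recording %s.", rec_id),
            class = "rehabrec_data_error")
    }
    ann <- dplyr::arrange(annotations[annotations$recording == rec_id, ],
                          .data$start)
    if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)])) {
      abort(sprintf("Overlapping annotated segments in recording %s.", rec_id),
            class = "rehabrec_data_error")
    }
    if (any(ann$end > nrow(sig))) {
      abort(sprintf("Annotation extends past the end of recording %s.", rec_id),
            class = "rehabrec_data_error")
    }
    h <- detection_channel(sig, smooth_length = smooth_length,
                           baseline = baseline)
    rep_max <- c(rep_max, purrr::map2_dbl(ann$start, ann$end,
                                          ~ max(h[.x:.y])))
    durations <- c(durations, ann$end - ann$start + 1L)
    if (nrow(ann) > 1L) {
      for (i in seq_len(nrow(ann) - 1L)) {
        lo <- ann$end[i] + 1L
        hi <- ann$start[i + 1L] - 1L
        if (lo <= hi) gap_min <- c(gap_min, min(h[lo:hi]))
      }
    }
  }

  t_p <- alpha * min(rep_max)
  d <- max(1L, as.integer(floor(beta * min(durations))))
  if (length(gap_min) == 0L) {
    warn("No inter-repetition gaps in the training set; valley threshold falls back to 0.2 * peak threshold.")
    t_v <- 0.2 * t_p
  } else {
    t_v <- gamma * max(gap_min)
  }
  if (t_p <= t_v) {
    abort(sprintf(
      paste0("Degenerate training data: learned peak threshold (%.4f g) does not ",
             "exceed the valley threshold (%.4f g). Repetition peaks and rest ",
             "gaps are not separable on the detection channel; check the ",
             "annotations or the baseline setting."),
      t_p, t_v
    ), class = "rehabrec_data_error")
  }
  if (boundary_type == "auto") {
    boundary_type <- if (length(gap_min) > 0L && median(gap_min) <= t_v) {
      "valley"
    } else {
      "peak"
    }
  }
  structure(list(peak_threshold = t_p,
                 min_peak_distance = d,
                 valley_threshold = t_v,
                 boundary_type = boundary_type,
                 smooth_length = as.integer(smooth_length),
                 baseline = baseline),
            class = "segmentation_params")
}

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf(
    paste0("# segmentation_params: T_p = %.4f g, D = %d samples, ",
           "T_v = %.4f g, %s boundaries\n"),
    x$peak_threshold, x$min_peak_distance, x$valley_threshold,
    x$boundary_type))
  invisible(x)
}

#' Dynamic per-repetition segmentation
#'
#' Splits a continuous recording into one segment per detected repetition
#' peak, so segment length tracks the duration of the underlying movement.
#' With valley boundaries, each segment spans from the valley nearest before
#' its peak to the valley nearest after it (falling back to the signal edge
#' when no valley exists on that side); a valley sample shared by two
#' consecutive segments is assigned to the earlier one. With peak
#' boundaries, segments span the midpoints between neighbouring peaks,
#' clipped to the signal extent.
#'
#' @param signal An [accel_signal()].
#' @param params A `segmentation_params` object from
#'   [learn_segmentation_params()].
#' @return Tibble of segments (`recording`, `subject_id`, `start`, `end`,
#'   `peak`), sorted, pairwise disjoint and within the recording; empty when
#'   no peaks are found.
#' @export
dynamic_segment <- function(signal, params) {
  stopifnot(inherits(signal, "accel_signal"),
            inherits(params, "segmentation_params"))
  if (params$peak_threshold <= params$valley_threshold) {
    abort("Segmentation parameters must satisfy peak_threshold > valley_threshold.",
          class = "rehabrec_parameter_error")
  }
  h <- detection_channel(signal, smooth_length = params$smooth_length,
                         baseline = params$baseline)
  peaks <- detect_peaks(h, params$peak_threshold, params$min_peak_distance)
  empty <- tibble(recording = character(0), subject_id = character(0),
                  start = integer(0), end = integer(0), peak = integer(0))
  if (length(peaks) == 0L) return(empty)
  n <- length(h)
  if (params$boundary_type == "valley") {
    valleys <- detect_valleys(h, params$valley_threshold)
    starts <- ends <- integer(length(peaks))
    for (i in seq_along(peaks)) {
      before <- valleys[valleys < peaks[i]]
      after <- valleys[valleys > peaks[i]]
      starts[i] <- if (length(before) > 0L) max(before) else 1L
      ends[i] <- if (length(after) > 0L) min(after) else n
    }
    # A shared boundary valley belongs to the earlier segment.
    if (length(peaks) > 1L) {
      shared <- which(starts[-1L] <= ends[-length(ends)])
      starts[shared + 1L] <- ends[shared] + 1L
    }
  } else {
    mids <- as.integer(floor((head(peaks, -1L) + tail(peaks, -1L)) / 2))
    starts <- c(1L, mids + 1L)
    ends <- c(mids, n)
  }
  keep <- starts <= ends
  tibble(recording = signal_recording(signal),
         subject_id = signal_subject(signal),
         start = starts[keep], end = ends[keep], peak = peaks[keep])
}

#' Fixed-length sliding-window segmentation
#'
#' The conventional baseline segmenter: windows of `length_s` seconds
#' starting every `round(L * (1 - overlap))` samples from the beginning of
#' the recording. All windows have exactly `L = round(length_s * fs)`
#' samples; a trailing remainder shorter than `L` is dropped rather than
#' padded, so no window carries length-biased features.
#'
#' @param signal An [accel_signal()].
#' @param length_s Window length in seconds (`> 0`).
#' @param overlap Fractional overlap between consecutive windows, in
#'   `[0, 1)`; 0.5 by default.
#' @return Tibble of segments (`recording`, `subject_id`, `start`, `end`),
#'   each of exactly `L` samples.
#' @export
#' @examples
#' s <- accel_signal((0:299) / 30, rnorm(300), rnorm(300), rnorm(300))
#' nrow(sliding_windows(s, 2))  # 9 windows of 60 samples
sliding_windows <- function(signal, length_s, overlap = 0.5) {
  stopifnot(inherits(signal, "accel_signal"))
  if (!is.numeric(length_s) || length_s <= 0) {
    abort("Window length must be a positive number of seconds.",
          class = "rehabrec_parameter_error")
  }
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    abort("Window overlap must lie in [0, 1).",
          class = "rehabrec_parameter_error")
  }
  n <- nrow(signal)
  l <- as.integer(round(length_s * signal_fs(signal)))
  if (l < 1L || l > n) {
    abort(sprintf(
      "Window of %g s is %d samples, outside [1, %d].", length_s, l, n
    ), class = "rehabrec_parameter_error")
  }
  stride <- max(1L, as.integer(round(l * (1 - overlap))))
  starts <- seq.int(1L, n - l + 1L, by = stride)
  tibble(recording = signal_recording(signal),
         subject_id = signal_subject(signal),
         start = as.integer(starts), end = as.integer(starts + l - 1L))
}

#' Interval intersection-over-union
#'
#' IoU of two 1-based inclusive sample intervals: intersection length over
#' union length.
#'
#' @param start1,end1,start2,end2 Interval endpoints (vectorized).
#' @return Numeric IoU in `[0, 1]`.
#' @export
segment_iou <- function(start1, end1, start2, end2) {
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  union <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  inter / union
}

#' Label detected segments against ground truth
#'
#' Matches detected segments to annotated (true) segments of the same
#' recording one-to-one, greedily by descending interval IoU. A detected
#' segment inherits the activity label of its matched truth segment when the
#' IoU is at least `min_iou`; unmatched detections are discarded.
#'
#' @param detected Tibble of detected segments (`recording`, `subject_id`,
#'   `start`, `end`).
#' @param truth Annotation tibble with pairwise-disjoint segments per
#'   recording.
#' @param min_iou Minimum IoU for a match (default 0.5).
#' @return Tibble of labeled segments (`recording`, `subject_id`,
#'   `activity`, `start`, `end`, `iou`, `truth_start`, `truth_end`), sorted
#'   by `(subject_id, recording, start)`.
#' @export
match_segments_to_labels <- function(detected, truth, min_iou = 0.5) {
  validate_annotations(truth)
  out <- list()
  for (rec_id in unique(detected$recording)) {
    det <- detected[detected$recording == rec_id, ]
    tru <- truth[truth$recording == rec_id, ]
    if (nrow(det) == 0L || nrow(tru) == 0L) next
    iou <- outer(seq_len(nrow(det)), seq_len(nrow(tru)), function(i, j) {
      segment_iou(det$start[i], det$end[i], tru$start[j], tru$end[j])
    })
    pairs <- which(iou >= min_iou, arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    ord <- order(-iou[pairs], pairs[, 1L], pairs[, 2L])
    used_det <- logical(nrow(det))
    used_tru <- logical(nrow(tru))
    rows <- list()
    for (k in ord) {
      i <- pairs[k, 1L]
      j <- pairs[k, 2L]
      if (used_det[i] || used_tru[j]) next
      used_det[i] <- TRUE
      used_tru[j] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        recording = rec_id,
        subject_id = tru$subject_id[j],
        activity = tru$activity[j],
        start = det$start[i], end = det$end[i],
        iou = iou[i, j],
        truth_start = tru$start[j], truth_end = tru$end[j])
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(rows)
  }
  if (length(out) == 0L) {
    return(tibble(recording = character(0), subject_id = character(0),
                  activity = as_activity(character(0)),
                  start = integer(0), end = integer(0), iou = numeric(0),
                  truth_start = integer(0), truth_end = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$subject_id, .data$recording,
                 .data$start)
}
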