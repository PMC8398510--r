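test_that("detect_peaks finds thresholded bumps and respects minimum distance", {
  ch <- bump_channel(300, centers = c(50, 200))
  expect_equal(detect_peaks(ch, threshold = 0.5, min_distance = 30),
               c(50L, 200L))
  expect_equal(detect_peaks(rep(0.1, 50) + bump_channel(50, 25, heights = 0.3),
                            threshold = 0.5, min_distance = 5), integer(0))
  # two bumps 10 samples apart with D = 30: only the higher one survives
  ch2 <- bump_channel(200, centers = c(100, 110), width = 3,
                      heights = c(0.8, 1.0))
  expect_equal(detect_peaks(ch2, threshold = 0.5, min_distance = 30), 110L)
  expect_error(detect_peaks(numeric(0), 0.5), class = "rehabrec_data_error")
  expect_error(detect_peaks(ch, 0.5, 0), class = "rehabrec_parameter_error")
})

test_that("detect_peaks agrees with a brute-force oracle on random channels", {
  set.seed(123)
  for (i in 1:30) {
    n <- sample(50:1000, 1)
    v <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2))
    v[is.na(v)] <- 0
    thr <- quantile(v, runif(1, 0.5, 0.95))
    d <- sample(1:40, 1)
    expect_equal(detect_peaks(v, thr, d), oracle_peaks(v, thr, d))
  }
})

test_that("detect_valleys returns thresholded local minima", {
  # constant channel: no local minima at all
  expect_equal(detect_valleys(rep(1, 50), threshold = 2), integer(0))
  v <- 1 - bump_channel(101, 51, width = 10, heights = 0.95)  # dips to 0.05
  expect_equal(detect_valleys(v, threshold = 0.2), 51L)
  expect_equal(detect_valleys(v, threshold = 0.01), integer(0))
  # rectified-sine-like channel: one valley per inter-bump gap
  ch <- bump_channel(400, centers = c(60, 180, 300), width = 12)
  vl <- detect_valleys(ch, threshold = 0.1)
  expect_equal(length(vl), 2L)
  expect_true(all(vl > 60 & vl < 300))
})

test_that("threshold learning follows the stated arithmetic", {
  # Reps are plateaus at 1.5 g lasting 60/80/100 samples, gaps dip to 0.1 g.
  rep_lens <- c(60, 80, 100)
  vals <- c(rep(0.1, 30))
  starts <- integer(3)
  for (i in 1:3) {
    starts[i] <- length(vals) + 1L
    vals <- c(vals, rep(1.5, rep_lens[i]), rep(0.1, 30))
  }
  sig <- carrier_signal(vals)
  ann <- tibble::tibble(recording = "r01", subject_id = "s01",
                        activity = as_activity(rep("SA", 3)),
                        start = starts, end = starts + rep_lens - 1L)
  params <- learn_segmentation_params(list(r01 = sig), ann,
                                      smooth_length = 1, baseline = "none")
  expect_equal(params$peak_threshold, 0.9 * 1.5)
  expect_equal(params$min_peak_distance, 48L)   # floor(0.8 * 60)
  expect_equal(params$valley_threshold, 1.5 * 0.1)
  expect_equal(params$boundary_type, "valley")  # gaps dip below T_v
})

test_that("threshold learning handles degenerate and gap-free training sets", {
  vals <- c(rep(0.1, 30), rep(1.5, 60), rep(0.1, 30))
  sig <- carrier_signal(vals)
  one <- tibble::tibble(recording = "r01", subject_id = "s01",
                        activity = as_activity("SA"),
                        start = 31L, end = 90L)
  expect_warning(
    p <- learn_segmentation_params(list(r01 = sig), one,
                                   smooth_length = 1, baseline = "none"),
    "falls back")
  expect_equal(p$valley_threshold, 0.2 * p$peak_threshold)

  overlapping <- dplyr::bind_rows(one, dplyr::mutate(one, start = 50L, end = 110L))
  expect_error(learn_segmentation_params(list(r01 = sig), overlapping,
                                         smooth_length = 1, baseline = "none"),
               class = "rehabrec_data_error")

  # gaps as high as the repetitions: thresholds cannot separate
  flat <- carrier_signal(rep(1.5, 200))
  two <- tibble::tibble(recording = "r01", subject_id = "s01",
                        activity = as_activity(c("SA", "SA")),
                        start = c(11L, 111L), end = c(70L, 170L))
  expect_error(learn_segmentation_params(list(r01 = flat), two,
                                         smooth_length = 1, baseline = "none"),
               class = "rehabrec_data_error")
  expect_error(learn_segmentation_params(list(r01 = flat), two[0, ]),
               class = "rehabrec_data_error")
})

test_that("dynamic segmentation returns sorted disjoint in-range segments", {
  params <- structure(list(peak_threshold = 0.5, min_peak_distance = 20L,
                           valley_threshold = 0.1, boundary_type = "valley",
                           smooth_length = 5L, baseline = "none"),
                      class = "segmentation_params")
  flat <- carrier_signal(rep(0, 300))
  expect_equal(nrow(dynamic_segment(flat, params)), 0L)

  set.seed(5)
  for (mode in c("valley", "peak")) {
    params$boundary_type <- mode
    for (i in 1:10) {
      n <- sample(100:800, 1)
      ch <- bump_channel(n, centers = sort(sample(30:(n - 30),
                                                  sample(1:6, 1))),
                         width = 8) + abs(rnorm(n, 0, 0.02))
      segs <- dynamic_segment(carrier_signal(ch), params)
      if (nrow(segs) > 1L) {
        expect_true(all(diff(segs$start) > 0))
        expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
      }
      expect_true(all(segs$start >= 1 & segs$end <= n & segs$start <= segs$end))
    }
  }

  bad <- params
  bad$peak_threshold <- 0.05
  bad$valley_threshold <- 0.1
  expect_error(dynamic_segment(flat, bad),
               class = "rehabrec_parameter_error")
})

test_that("detected segment length tracks repetition duration", {
  # second bump 1.5x wider than the first
  ch <- bump_channel(500, 120, width = 12) +
    bump_channel(500, 350, width = 18)
  params <- structure(list(peak_threshold = 0.5, min_peak_distance = 60L,
                           valley_threshold = 0.05, boundary_type = "valley",
                           smooth_length = 1L, baseline = "none"),
                      class = "segmentation_params")
  segs <- dynamic_segment(carrier_signal(ch), params)
  expect_equal(nrow(segs), 2L)
  len <- segs$end - segs$start + 1
  expect_gte(len[2], 1.2 * len[1])
})

test_that("sliding windows have the exact count, length and stride", {
  sig <- random_signal(300)
  w <- sliding_windows(sig, length_s = 2, overlap = 0.5)
  expect_equal(nrow(w), 9L)                       # (300 - 60) / 30 + 1
  expect_equal(w$start, seq(1L, 241L, by = 30L))
  expect_true(all(w$end - w$start + 1 == 60L))

  w0 <- sliding_windows(sig, length_s = 2, overlap = 0)
  expect_true(all(w0$start[-1] == w0$end[-nrow(w0)] + 1L))  # disjoint tiling
  expect_equal(nrow(w0) * 60L, floor(300 / 60) * 60L)

  w1 <- sliding_windows(sig, length_s = 10, overlap = 0.5)  # N / fs seconds
  expect_equal(nrow(w1), 1L)
  expect_error(sliding_windows(sig, length_s = 11),
               class = "rehabrec_parameter_error")
  expect_error(sliding_windows(sig, 2, overlap = 1),
               class = "rehabrec_parameter_error")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(60:2000, 1)
    ls <- runif(1, 0.5, n / 30)
    ov <- runif(1, 0, 0.9)
    l <- round(ls * 30)
    if (l < 1 || l > n) next
    stride <- max(1, round(l * (1 - ov)))
    expect_equal(nrow(sliding_windows(random_signal(n), ls, ov)),
                 floor((n - l) / stride) + 1)
  }
})

test_that("segment labeling is one-to-one by descending IoU", {
  truth <- tibble::tibble(recording = "r01", subject_id = "s01",
                          activity = as_activity(c("SA", "EE")),
                          start = c(1L, 71L), end = c(70L, 100L))
  # perfect detection: identical labels, IoU 1
  det <- truth[, c("recording", "subject_id", "start", "end")]
  lab <- match_segments_to_labels(det, truth)
  expect_equal(as.character(lab$activity), c("SA", "EE"))
  expect_equal(lab$iou, c(1, 1))

  # a segment overlapping nothing is discarded
  det2 <- tibble::tibble(recording = "r01", subject_id = "s01",
                         start = 200L, end = 260L)
  expect_equal(nrow(match_segments_to_labels(det2, truth)), 0L)

  # a 100-sample detection straddling the 70/30 split labels as the 70% side
  det3 <- tibble::tibble(recording = "r01", subject_id = "s01",
                         start = 1L, end = 100L)
  lab3 <- match_segments_to_labels(det3, truth, min_iou = 0.5)
  expect_equal(as.character(lab3$activity), "SA")
  expect_equal(lab3$iou, 0.7)
})

test_that("interval IoU arithmetic is correct", {
  expect_equal(segment_iou(1, 10, 6, 15), 5 / 15)
  expect_equal(segment_iou(1, 10, 1, 10), 1)
  expect_equal(segment_iou(1, 10, 11, 20), 0)
})
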