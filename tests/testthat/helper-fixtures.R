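# Shared fixture builders. Everything is generated in code; no data files.

# Signal whose magnitude equals `values` (x = values, y = z = 0).
carrier_signal <- function(values, fs = 30, subject_id = "s01",
                           recording_id = "r01") {
  accel_signal(time_s = (seq_along(values) - 1) / fs,
               x_g = values, y_g = rep(0, length(values)),
               z_g = rep(0, length(values)), fs = fs,
               subject_id = subject_id, recording_id = recording_id)
}

random_signal <- function(n, fs = 30, sd = 0.3, subject_id = "s01",
                          recording_id = "r01") {
  accel_signal(time_s = (seq_len(n) - 1) / fs,
               x_g = rnorm(n, 0, sd), y_g = rnorm(n, 0, sd),
               z_g = rnorm(n, 1, sd), fs = fs,
               subject_id = subject_id, recording_id = recording_id)
}

# Unit-height Gaussian bumps centered at `centers`.
bump_channel <- function(n, centers, width = 8, heights = 1) {
  heights <- rep_len(heights, length(centers))
  v <- numeric(n)
  for (i in seq_along(centers)) {
    v <- v + heights[i] * exp(-((seq_len(n) - centers[i])^2) / (2 * width^2))
  }
  v
}

# Linearly separable two-class feature table: class A sits at 0, class B at
# `offset`, in every feature, plus small jitter.
separable_table <- function(n_per = 10, offset = 10, seed = 99) {
  set.seed(seed)
  feats <- matrix(rnorm(2 * n_per * 24, sd = 0.1), ncol = 24)
  feats[(n_per + 1):(2 * n_per), ] <- feats[(n_per + 1):(2 * n_per), ] + offset
  colnames(feats) <- feature_names()
  dplyr::bind_cols(
    tibble::tibble(subject_id = rep(c("sA", "sB"), each = n_per),
                   recording = rep(c("rA", "rB"), each = n_per),
                   activity = rep(c("SA", "EE"), each = n_per)),
    tibble::as_tibble(feats))
}

# Brute-force peak oracle: all strict local maxima >= threshold, kept
# greedily highest-first (earlier index on ties), suppressing within D.
oracle_peaks <- function(v, threshold, d) {
  n <- length(v)
  cand <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && v[i] > v[i - 1] && v[i] > v[i + 1] && v[i] >= threshold
  }, logical(1)))
  kept <- integer(0)
  for (i in cand[order(-v[cand], cand)]) {
    if (all(abs(kept - i) >= d)) kept <- c(kept, i)
  }
  sort(kept)
}

# Brute-force per-sample metric counter, independent of the matrix algebra.
oracle_metrics <- function(truth, pred, classes) {
  recall <- precision <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    recall[i] <- tp / (tp + fn)
    precision[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1[i] <- if (precision[i] + recall[i] == 0) 0 else
      2 * precision[i] * recall[i] / (precision[i] + recall[i])
  }
  list(accuracy = mean(truth == pred), recall = recall,
       precision = precision, f1 = f1)
}

tiny_study <- function(n_subjects = 3, n_reps = 3, seed = 11, ...) {
  simulate_study(study_design(n_subjects = n_subjects, n_reps = n_reps,
                              seed = seed, ...))
}
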