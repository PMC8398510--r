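#' Moving-average smoothing
#'
#' Replaces each acceleration channel by its trailing (causal) moving mean.
#' The first `length - 1` samples average over the partial window of all
#' samples seen so far, so the output has the same length as the input and
#' stays aligned with the original sample indices. A window of 10 samples
#' (1/3 s at 30 Hz) is the default, which suppresses sensor noise without
#' blurring repetition structure.
#'
#' @param signal An [accel_signal()].
#' @param length Window length in samples (default 10); must lie in
#'   `[1, n_samples(signal)]`.
#' @return A smoothed [accel_signal()] with unchanged sampling rate.
#' @export
#' @examples
#' s <- accel_signal((0:3) / 30, x_g = c(1, 2, 3, 4), y_g = rep(0, 4),
#'                   z_g = rep(1, 4))
#' moving_average(s, length = 2)$x_g  # 1.0 1.5 2.5 3.5
moving_average <- function(signal, length = 10L) {
  stopifnot(inherits(signal, "accel_signal"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L || length > nrow(signal)) {
    abort(sprintf(
      "Moving-average length must be an integer in [1, %d]; got %s.",
      nrow(signal), length
    ), class = "rehabrec_parameter_error")
  }
  rebuild_signal(signal,
                 x_g = trailing_mean(signal$x_g, length),
                 y_g = trailing_mean(signal$y_g, length),
                 z_g = trailing_mean(signal$z_g, length))
}

# Trailing mean with partial windows at the start: O(n) via cumulative sums.
trailing_mean <- function(x, len) {
  if (len == 1L) return(x)
  n <- length(x)
  cs <- cumsum(x)
  denom <- pmin(seq_len(n), len)
  lagged <- c(rep(0, len), head(cs, n - len))[seq_len(n)]
  (cs - lagged) / denom
}

# Centered moving mean (zero phase), partial windows at both edges. Used
# internally for the segmentation detection channel so boundary estimates
# carry no group delay.
centered_mean <- function(x, len) {
  if (len <= 1L) return(x)
  n <- length(x)
  half_l <- (len - 1L) %/% 2L
  half_r <- len - 1L - half_l
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Acceleration magnitude
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three
#' acceleration axes, in g. On wrist data at rest the magnitude sits near
#' 1 g (gravity); exercise repetitions appear as excursions above it.
#'
#' @param signal An [accel_signal()].
#' @return Numeric vector of magnitudes, one per sample, all `>= 0`.
#' @export
#' @examples
#' s <- accel_signal(0, x_g = 3, y_g = 4, z_g = 0)
#' signal_magnitude(s)  # 5
signal_magnitude <- function(signal) {
  stopifnot(inherits(signal, "accel_signal"))
  sqrt(signal$x_g^2 + signal$y_g^2 + signal$z_g^2)
}
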