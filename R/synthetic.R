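#' Synthetic study design
#'
#' Parameters of the emulated data-collection protocol: `n_subjects`
#' subjects each performing `n_reps` repetitions of the seven exercises
#' while wearing a wrist accelerometer sampling at `fs` Hz with a hard
#' `+/- clip_g` g range. Defaults reproduce the reference protocol: 10
#' subjects x 10 repetitions x 7 activities = 700 labeled repetitions at
#' 30 Hz, +/- 2 g.
#'
#' Subject-to-subject variation is drawn per subject: an overall amplitude
#' scale and duration scale (uniform on `amplitude_scale_range` /
#' `duration_scale_range`), a random sensor-orientation rotation (random
#' axis, angle ~ Normal(0, `rotation_sd_deg`)) and a white-noise level
#' (uniform on `noise_range`, in g). Repetitions are separated by rest gaps
#' drawn uniformly from `rest_gap_s` seconds.
#'
#' @param n_subjects,n_reps Protocol size (defaults 10 and 10).
#' @param fs Sampling rate in Hz (default 30).
#' @param seed Integer seed; every random draw of the study derives from it.
#' @param confusability In `[0, 0.5]`: how similar the SA and SF templates
#'   are (0 = orthogonal movement directions, 0.5 = identical); default 0.15.
#' @param noise_range Per-subject white-noise sigma range in g
#'   (default `c(0.02, 0.06)`).
#' @param rest_gap_s Inter-repetition rest-gap range in seconds
#'   (default `c(0.5, 1.5)`).
#' @param clip_g Hard sensor range in g (default 2).
#' @param amplitude_scale_range,duration_scale_range Per-subject scale
#'   ranges (defaults `c(0.85, 1.15)`).
#' @param rotation_sd_deg Standard deviation of the per-subject orientation
#'   angle in degrees (default 8).
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 10L, n_reps = 10L, fs = 30,
                         seed = 42L, confusability = 0.15,
                         noise_range = c(0.02, 0.06),
                         rest_gap_s = c(0.5, 1.5), clip_g = 2,
                         amplitude_scale_range = c(0.85, 1.15),
                         duration_scale_range = c(0.85, 1.15),
                         rotation_sd_deg = 8) {
  stopifnot(n_subjects >= 1L, n_reps >= 1L, fs > 0, clip_g > 0,
            confusability >= 0, confusability <= 0.5)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_reps = as.integer(n_reps), fs = fs,
                 seed = as.integer(seed), confusability = confusability,
                 noise_range = noise_range, rest_gap_s = rest_gap_s,
                 clip_g = clip_g,
                 amplitude_scale_range = amplitude_scale_range,
                 duration_scale_range = duration_scale_range,
                 rotation_sd_deg = rotation_sd_deg),
            class = "study_design")
}

# Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# Direction from transverse azimuth (degrees) and z component.
dir_from <- function(azimuth_deg, z) {
  r <- sqrt(1 - z^2)
  a <- azimuth_deg * pi / 180
  c(r * cos(a), r * sin(a), z)
}

#' Activity waveform templates
#'
#' Each of the seven exercises is realized as a smooth unimodal
#' (raised-cosine) acceleration burst with an activity-specific duration,
#' amplitude, 3-D movement direction and small per-axis phase lags. SA and
#' SF share duration, amplitude, envelope and lags and differ *only* by a
#' rotation of the movement direction whose angle is controlled by
#' `confusability`: 90 degrees (orthogonal directions) at 0, shrinking to 0
#' (identical templates) at 0.5. All other activity pairs differ in at least
#' two of duration, dominant axis and amplitude. The peak magnitude of every
#' noiseless template equals its amplitude, inside (0.3, 2] g.
#'
#' @param confusability Fraction in `[0, 0.5]` (default 0.15).
#' @return Tibble with one row per activity: `activity`, `duration_mean_s`,
#'   `duration_spread`, `amplitude`, `dir_x/y/z` (unit movement direction)
#'   and `lag_x/y/z` (per-axis phase lags as fractions of the burst
#'   duration).
#' @export
make_templates <- function(confusability = 0.15) {
  stopifnot(confusability >= 0, confusability <= 0.5)
  sa_dir <- dir_from(10, 0.62)
  # Axis-mixing rotation for SF, about a fixed axis perpendicular to the SA
  # direction; the mapping is steep near 0.5 so the default of 0.15 yields
  # a deliberately similar -- but not identical -- pair.
  theta <- (pi / 2) * (1 - 2 * confusability)^4
  rot_axis <- normalize3(pracma_cross(sa_dir, c(0, 0, 1)))
  sf_dir <- as.vector(rotation_matrix(rot_axis, -theta) %*% sa_dir)
  dirs <- rbind(
    SA = sa_dir,
    EE = dir_from(135, 0.50),
    EF = dir_from(100, 0.70),
    SER = dir_from(200, 0.55),
    SIR = dir_from(250, 0.72),
    SE = dir_from(305, 0.45),
    SF = sf_dir)
  tpl <- tibble(
    activity = activity_levels(),
    duration_mean_s = c(2.8, 2.1, 3.2, 2.5, 3.0, 3.5, 2.8),
    duration_spread = 0.1,
    amplitude = c(1.05, 0.85, 1.20, 1.00, 1.15, 0.90, 1.05),
    dir_x = dirs[activity_levels(), 1],
    dir_y = dirs[activity_levels(), 2],
    dir_z = dirs[activity_levels(), 3],
    lag_x = c(0, 0.04, 0, 0.05, 0, 0.03, 0),
    lag_y = c(0.04, 0, 0.05, 0, 0.04, 0, 0.04),
    lag_z = c(0.02, 0.02, 0.03, 0.02, 0.06, 0.05, 0.02))
  tpl
}

# Cross product (avoids pulling in a linear-algebra dependency for one op).
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Draw a subject profile
#'
#' Draws one subject's variation parameters from the design's
#' distributions, consuming the current RNG stream.
#'
#' @param subject_id Label for the subject.
#' @param design A [study_design()].
#' @return A `subject_profile` list: `subject_id`, `amplitude_scale`,
#'   `duration_scale`, `rotation` (3 x 3 matrix), `rotation_deg`,
#'   `noise_sigma`.
#' @export
subject_profile <- function(subject_id, design = study_design()) {
  amp <- runif(1, design$amplitude_scale_range[1],
               design$amplitude_scale_range[2])
  dur <- runif(1, design$duration_scale_range[1],
               design$duration_scale_range[2])
  ax <- rnorm(3)
  angle <- rnorm(1, 0, design$rotation_sd_deg) * pi / 180
  rot <- if (design$rotation_sd_deg > 0) {
    rotation_matrix(normalize3(ax), angle)
  } else {
    diag(3)
  }
  sigma <- runif(1, design$noise_range[1], design$noise_range[2])
  structure(list(subject_id = subject_id, amplitude_scale = amp,
                 duration_scale = dur, rotation = rot,
                 rotation_deg = angle * 180 / pi, noise_sigma = sigma),
            class = "subject_profile")
}

# Raised-cosine envelope on [0, 1], zero outside.
burst_envelope <- function(u) {
  ifelse(u >= 0 & u <= 1, sin(pi * u)^2, 0)
}

#' Simulate one recording
#'
#' Generates a continuous recording of `n_reps` repetitions of one activity
#' by one subject: a gravity baseline of 1 g along the sensor z axis
#' (rotated by the subject's orientation), plus a sequence of scaled and
#' duration-warped template bursts separated by rest gaps, plus white
#' Gaussian noise, hard-clipped to the sensor range. Consumes the current
#' RNG stream; seed it for reproducibility.
#'
#' @param profile A [subject_profile()].
#' @param activity One of [activity_levels()].
#' @param n_reps Number of repetitions (`>= 1`).
#' @param design A [study_design()].
#' @param templates Template table from [make_templates()]; defaults to
#'   `make_templates(design$confusability)`.
#' @return List with `signal` (an [accel_signal()]) and `annotations`
#'   (ground-truth labeled segments, disjoint and inside the recording).
#' @export
simulate_recording <- function(profile, activity, n_reps,
                               design = study_design(),
                               templates = NULL) {
  stopifnot(inherits(profile, "subject_profile"), n_reps >= 1L)
  templates <- templates %||% make_templates(design$confusability)
  tpl <- templates[templates$activity == activity, ]
  if (nrow(tpl) != 1L) {
    abort(sprintf("No template for activity %s.", activity),
          class = "rehabrec_data_error")
  }
  fs <- design$fs
  dir_rot <- as.vector(profile$rotation %*%
                         c(tpl$dir_x, tpl$dir_y, tpl$dir_z))
  gravity <- as.vector(profile$rotation %*% c(0, 0, 1))
  lags <- c(tpl$lag_x, tpl$lag_y, tpl$lag_z)

  # Per-repetition randomization, then assembly.
  gaps <- runif(n_reps + 1L, design$rest_gap_s[1], design$rest_gap_s[2])
  dur_s <- tpl$duration_mean_s * profile$duration_scale *
    runif(n_reps, 1 - tpl$duration_spread, 1 + tpl$duration_spread)
  amp <- tpl$amplitude * profile$amplitude_scale * runif(n_reps, 0.93, 1.07)
  gap_len <- pmax(1L, as.integer(round(gaps * fs)))
  burst_core <- pmax(2L, as.integer(round(dur_s * fs)))
  burst_len <- as.integer(ceiling(burst_core * (1 + max(lags))))

  n <- sum(gap_len) + sum(burst_len)
  acc <- matrix(rep(gravity, each = n), nrow = n)
  starts <- integer(n_reps)
  pos <- 1L
  for (r in seq_len(n_reps)) {
    pos <- pos + gap_len[r]
    starts[r] <- pos
    u <- (seq_len(burst_len[r]) - 1L) / (burst_core[r] - 1L)
    for (axis in 1:3) {
      acc[pos:(pos + burst_len[r] - 1L), axis] <-
        acc[pos:(pos + burst_len[r] - 1L), axis] +
        amp[r] * dir_rot[axis] * burst_envelope(u - lags[axis])
    }
    pos <- pos + burst_len[r]
  }
  if (profile$noise_sigma > 0) {
    acc <- acc + matrix(rnorm(3L * n, 0, profile$noise_sigma), nrow = n)
  }
  acc <- pmin(pmax(acc, -design$clip_g), design$clip_g)

  rec_id <- paste(profile$subject_id, activity, sep = "_")
  signal <- accel_signal((seq_len(n) - 1L) / fs, acc[, 1], acc[, 2],
                         acc[, 3], fs = fs,
                         subject_id = profile$subject_id,
                         recording_id = rec_id)
  annotations <- tibble(
    recording = rec_id,
    subject_id = profile$subject_id,
    activity = as_activity(rep(activity, n_reps)),
    start = starts,
    end = starts + burst_len - 1L)
  list(signal = signal, annotations = annotations)
}

#' Simulate a complete labeled study
#'
#' Generates one recording per (subject, activity) under the given design:
#' `n_subjects * n_reps * 7` labeled repetitions in total. Each subject's
#' RNG substream is derived deterministically from the design seed and the
#' subject index, so the study is byte-identical across runs with the same
#' seed and adding subjects does not perturb earlier subjects' data.
#'
#' @param design A [study_design()].
#' @return A [rehab_study()].
#' @export
#' @examples
#' study <- simulate_study(study_design(n_subjects = 2, n_reps = 2))
#' nrow(study$annotations)  # 2 * 2 * 7 = 28
simulate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  templates <- make_templates(design$confusability)
  recordings <- list()
  annotations <- list()
  for (i in seq_len(design$n_subjects)) {
    sid <- sprintf("s%02d", i)
    set.seed((design$seed + 104729L * i) %% .Machine$integer.max)
    profile <- subject_profile(sid, design)
    for (act in activity_levels()) {
      rec <- simulate_recording(profile, act, design$n_reps, design,
                                templates)
      recordings[[signal_recording(rec$signal)]] <- rec$signal
      annotations[[length(annotations) + 1L]] <- rec$annotations
    }
  }
  rehab_study(recordings, dplyr::bind_rows(annotations))
}
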