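test_that("the protocol arithmetic holds for small designs", {
  study <- simulate_study(study_design(n_subjects = 2, n_reps = 1, seed = 5))
  expect_equal(nrow(study$annotations), 2 * 1 * 7)
  expect_equal(length(study$recordings), 14L)
  study2 <- simulate_study(study_design(n_subjects = 1, n_reps = 4, seed = 5))
  expect_equal(nrow(study2$annotations), 28L)
})

test_that("the generator is deterministic and subject-stable under a seed", {
  a <- simulate_study(study_design(n_subjects = 2, n_reps = 2, seed = 42))
  b <- simulate_study(study_design(n_subjects = 2, n_reps = 2, seed = 42))
  expect_identical(a$annotations, b$annotations)
  for (id in names(a$recordings)) {
    expect_identical(as.data.frame(a$recordings[[id]]),
                     as.data.frame(b$recordings[[id]]))
  }
  # adding a subject does not perturb earlier subjects' data
  c3 <- simulate_study(study_design(n_subjects = 3, n_reps = 2, seed = 42))
  expect_identical(as.data.frame(a$recordings[["s01_SA"]]),
                   as.data.frame(c3$recordings[["s01_SA"]]))
  expect_identical(as.data.frame(a$recordings[["s02_SF"]]),
                   as.data.frame(c3$recordings[["s02_SF"]]))
})

test_that("recordings respect the sensor range and truth segments are consistent", {
  study <- tiny_study(n_subjects = 2, n_reps = 4, seed = 17)
  for (id in names(study$recordings)) {
    sig <- study$recordings[[id]]
    expect_true(all(abs(sig$x_g) <= 2 & abs(sig$y_g) <= 2 &
                      abs(sig$z_g) <= 2))
    ann <- study$annotations[study$annotations$recording == id, ]
    expect_equal(nrow(ann), 4L)
    expect_true(all(ann$start >= 1 & ann$end <= nrow(sig)))
    ord <- order(ann$start)
    expect_true(all(ann$start[ord][-1] > ann$end[ord][-nrow(ann)]))
  }
})

test_that("noiseless rest gaps sit at exactly 1 g of gravity", {
  design <- study_design(n_subjects = 1, n_reps = 3, seed = 2,
                         noise_range = c(0, 0))
  set.seed(1)
  profile <- subject_profile("s01", design)
  rec <- simulate_recording(profile, "SA", 3, design)
  in_rep <- unlist(purrr::map2(rec$annotations$start, rec$annotations$end,
                               seq))
  rest <- setdiff(seq_len(nrow(rec$signal)), in_rep)
  m <- signal_magnitude(rec$signal)
  expect_true(all(abs(m[rest] - 1) < 1e-6))
})

test_that("templates cover all activities with bounded amplitudes and durations", {
  tpl <- make_templates()
  expect_equal(tpl$activity, activity_levels())
  expect_true(all(tpl$amplitude > 0.3 & tpl$amplitude <= 2))
  expect_true(all(tpl$duration_mean_s >= 1.5 & tpl$duration_mean_s <= 4))
  dirs <- as.matrix(tpl[, c("dir_x", "dir_y", "dir_z")])
  expect_equal(unname(sqrt(rowSums(dirs^2))), rep(1, 7), tolerance = 1e-9)
})

test_that("confusability controls the SA-SF movement-direction similarity", {
  t0 <- make_templates(confusability = 0)
  d_sa <- unlist(t0[t0$activity == "SA", c("dir_x", "dir_y", "dir_z")])
  d_sf <- unlist(t0[t0$activity == "SF", c("dir_x", "dir_y", "dir_z")])
  expect_lte(abs(sum(d_sa * d_sf)), 0.2)   # orthogonal directions

  t5 <- make_templates(confusability = 0.5)
  d_sf5 <- unlist(t5[t5$activity == "SF", c("dir_x", "dir_y", "dir_z")])
  expect_equal(sum(d_sa * d_sf5), 1, tolerance = 1e-9)  # identical

  # similarity increases monotonically with confusability
  sims <- vapply(c(0, 0.15, 0.3, 0.5), function(cf) {
    tt <- make_templates(cf)
    sum(unlist(tt[tt$activity == "SA", c("dir_x", "dir_y", "dir_z")]) *
          unlist(tt[tt$activity == "SF", c("dir_x", "dir_y", "dir_z")]))
  }, numeric(1))
  expect_true(all(diff(sims) > 0))

  # SA and SF otherwise share duration, amplitude and lags
  expect_equal(t0$duration_mean_s[t0$activity == "SA"],
               t0$duration_mean_s[t0$activity == "SF"])
  expect_equal(t0$amplitude[t0$activity == "SA"],
               t0$amplitude[t0$activity == "SF"])
})

test_that("subject profiles stay inside the documented variation ranges", {
  design <- study_design()
  set.seed(99)
  for (i in 1:20) {
    p <- subject_profile(sprintf("s%02d", i), design)
    expect_true(p$amplitude_scale >= 0.7 && p$amplitude_scale <= 1.3)
    expect_true(p$duration_scale >= 0.7 && p$duration_scale <= 1.3)
    expect_true(p$noise_sigma >= 0.01 && p$noise_sigma <= 0.08)
    expect_equal(det(p$rotation), 1, tolerance = 1e-9)
  }
})
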