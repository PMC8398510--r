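test_that("confusion matrices are built in canonical order", {
  cm <- confusion_matrix(c("SA", "SA"), c("SA", "SF"))
  expect_equal(rownames(cm$counts), activity_levels())
  expect_equal(unname(cm$counts["SA", "SA"]), 1)
  expect_equal(unname(cm$counts["SA", "SF"]), 1)
  expect_equal(sum(cm$counts), 2)

  pred <- sample(activity_levels(), 70, replace = TRUE)
  diagonal <- confusion_matrix(pred, pred)
  expect_true(all(diagonal$counts[upper.tri(diagonal$counts)] == 0))
  expect_true(all(diagonal$counts[lower.tri(diagonal$counts)] == 0))

  expect_error(confusion_matrix("SA", c("SA", "SF")),
               class = "rehabrec_parameter_error")
  expect_error(confusion_matrix(character(0), character(0)),
               class = "rehabrec_parameter_error")

  # with 100 samples per class, the percentage view equals the counts
  truth <- rep(activity_levels(), each = 100)
  balanced <- confusion_matrix(truth, truth)
  expect_equal(confusion_percent(balanced), balanced$counts)
})

test_that("metric arithmetic agrees with a brute-force per-sample counter", {
  set.seed(55)
  classes <- activity_levels()
  for (i in 1:25) {
    n <- sample(20:500, 1)
    truth <- sample(classes, n, replace = TRUE)
    while (length(unique(truth)) < 7) truth <- sample(classes, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, truth, sample(classes, n, replace = TRUE))
    mets <- suppressWarnings(
      metrics_from_confusion(confusion_matrix(truth, pred)))
    oracle <- oracle_metrics(truth, pred, classes)
    expect_equal(mets$accuracy, oracle$accuracy)
    expect_equal(mets$per_class$recall, oracle$recall)
    expect_equal(mets$per_class$precision, oracle$precision)
    expect_equal(mets$per_class$f1, oracle$f1)
    expect_equal(mets$macro_recall, mean(oracle$recall))
  }
})

test_that("perfect and degenerate confusion matrices follow the documented policy", {
  truth <- rep(activity_levels(), each = 3)
  perfect <- metrics_from_confusion(confusion_matrix(truth, truth))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(perfect$per_class$recall == 1))

  # SF never predicted: precision 0 with a warning, F1 0
  pred <- ifelse(truth == "SF", "SA", truth)
  expect_warning(mets <- metrics_from_confusion(confusion_matrix(truth, pred)),
                 "never predicted")
  expect_equal(mets$per_class$precision[mets$per_class$activity == "SF"], 0)
  expect_equal(mets$per_class$f1[mets$per_class$activity == "SF"], 0)

  # a class with no actual samples is rejected
  cm <- confusion_matrix(c("SA", "EE"), c("SA", "EE"))
  expect_error(metrics_from_confusion(cm),
               class = "rehabrec_parameter_error")
})

test_that("accuracy equals macro recall exactly on balanced data", {
  set.seed(77)
  for (i in 1:10) {
    truth <- rep(activity_levels(), each = 20)
    pred <- ifelse(runif(length(truth)) < 0.8, truth,
                   sample(activity_levels(), length(truth), replace = TRUE))
    mets <- suppressWarnings(
      metrics_from_confusion(confusion_matrix(truth, pred)))
    expect_equal(mets$accuracy, mets$macro_recall)
  }
})

test_that("confusion CSVs round-trip and blank cells parse as zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("actual,SA,EE,EF,SER,SIR,SE,SF",
               "SA,96,1,,,,,3",
               "EE,,99,,,1,,",
               "EF,,,99,,,1,",
               "SER,9,2,,89,,,",
               "SIR,1,2,,,97,,",
               "SE,,,3,3,,94,",
               "SF,10,,,,,,90"), path)
  cm <- read_confusion_csv(path)
  expect_equal(unname(cm$counts["SA", "EF"]), 0)
  expect_equal(unname(cm$counts["SER", "SA"]), 9)
  expect_equal(sum(cm$counts), 700)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path2, percent = FALSE)
  back <- read_confusion_csv(path2)
  expect_equal(back$counts, cm$counts)
})

test_that("stratified k-fold CV is deterministic and exhaustive", {
  tab <- separable_table(n_per = 12)
  cv <- kfold_cv(tab, classifier_spec("rf"), k = 4, seed = 10)
  expect_equal(nrow(cv$folds), 4L)
  expect_equal(sum(cv$folds$n_test), nrow(tab))      # each row tested once
  expect_equal(sum(cv$pooled$counts), nrow(tab))
  expect_equal(mean(cv$folds$accuracy), 1)

  cv2 <- kfold_cv(tab, classifier_spec("rf"), k = 4, seed = 10)
  expect_identical(cv$folds, cv2$folds)

  expect_error(kfold_cv(tab, k = 13), class = "rehabrec_data_error")
  expect_error(kfold_cv(tab, k = 1), class = "rehabrec_parameter_error")

  # k equal to the class size behaves as leave-one-out within classes
  loo <- kfold_cv(tab, classifier_spec("knn"), k = 12, seed = 2)
  expect_equal(sum(loo$folds$n_test), nrow(tab))
})

test_that("leave-one-subject-out holds every subject out exactly once", {
  study <- tiny_study(n_subjects = 3, n_reps = 3, seed = 21)
  cv <- loso_cv(study, classifier_spec("rf"), segmentation = "annotation")
  expect_equal(nrow(cv$folds), 3L)
  expect_setequal(cv$folds$subject_id, unique(study$annotations$subject_id))
  expect_equal(sum(cv$pooled$counts), sum(cv$folds$n_test))
  expect_error(loso_cv(rehab_study(study$recordings[1:7],
                                   study$annotations[1:21, ]),
                       classifier_spec("rf")),
               class = "rehabrec_data_error")  # single subject
})

test_that("two clone subjects with separable classes score perfectly", {
  one <- tiny_study(n_subjects = 1, n_reps = 3, seed = 4,
                    noise_range = c(0, 0))
  recs <- one$recordings
  ann <- one$annotations
  clone_recs <- recs
  names(clone_recs) <- sub("s01", "s02", names(recs))
  for (i in seq_along(clone_recs)) {
    attr(clone_recs[[i]], "subject_id") <- "s02"
    attr(clone_recs[[i]], "recording_id") <- names(clone_recs)[i]
  }
  clone_ann <- dplyr::mutate(ann, subject_id = "s02",
                             recording = sub("s01", "s02", recording))
  study <- rehab_study(c(recs, clone_recs),
                       dplyr::bind_rows(ann, clone_ann))
  cv <- loso_cv(study, classifier_spec("rf"))
  expect_equal(mean(cv$folds$accuracy), 1)
})

test_that("fold aggregation is invariant to subject labeling order", {
  study <- tiny_study(n_subjects = 3, n_reps = 3, seed = 13)
  cv1 <- loso_cv(study, classifier_spec("rf"))
  shuffled <- rehab_study(rev(study$recordings),
                          study$annotations[rev(seq_len(nrow(study$annotations))), ])
  cv2 <- loso_cv(shuffled, classifier_spec("rf"))
  expect_equal(cv1$aggregate, cv2$aggregate)
  expect_equal(cv1$pooled$counts, cv2$pooled$counts)
})
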