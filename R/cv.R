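new_rehab_cv <- function(folds, pooled_cm, mode, algorithm,
                         recovery = NULL) {
  agg <- tibble(
    metric = c("accuracy", "macro_recall", "macro_precision", "macro_f1"),
    mean = c(mean(folds$accuracy), mean(folds$macro_recall),
             mean(folds$macro_precision), mean(folds$macro_f1)),
    sd = c(sd(folds$accuracy), sd(folds$macro_recall),
           sd(folds$macro_precision), sd(folds$macro_f1)))
  structure(list(folds = folds, aggregate = agg, pooled = pooled_cm,
                 mode = mode, algorithm = algorithm, recovery = recovery),
            class = "rehab_cv")
}

#' @export
print.rehab_cv <- function(x, ...) {
  cat(sprintf("# rehab_cv (%s, %s): %d folds\n", x$mode, x$algorithm,
              nrow(x$folds)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-16s %.4f +/- %.4f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' @rdname tidy_rehabrec
#' @method tidy rehab_cv
#' @export
tidy.rehab_cv <- function(x, ...) x$folds

#' @rdname tidy_rehabrec
#' @method glance rehab_cv
#' @export
glance.rehab_cv <- function(x, ...) {
  agg <- x$aggregate
  out <- as.list(setNames(agg$mean, agg$metric))
  out <- c(out, as.list(setNames(agg$sd, paste0(agg$metric, "_sd"))))
  dplyr::bind_cols(tibble(mode = x$mode, algorithm = x$algorithm,
                          n_folds = nrow(x$folds)),
                   as_tibble(out))
}

# Per-fold metrics over the classes actually present in the fold's truth,
# so degenerate folds (a class entirely unrecovered) do not error out.
fold_metrics <- function(truth, pred) {
  present <- intersect(activity_levels(), unique(as.character(truth)))
  cm <- confusion_matrix(truth, pred, classes = activity_levels())
  sub <- new_confusion(cm$counts[present, present, drop = FALSE], present)
  withCallingHandlers(
    metrics_from_confusion(sub),
    warning = function(w) invokeRestart("muffleWarning"))
}

#' Leave-one-subject-out cross-validation of the full pipeline
#'
#' Each subject is held out exactly once. Within each fold, every learned
#' component — the segmentation thresholds, the feature scaler and the
#' classifier — is fitted only on the training subjects, then applied to the
#' held-out subject's recordings: the recordings are segmented
#' (dynamically, or with the sliding-window baseline), detected segments are
#' labeled against the ground-truth annotations at `min_iou`, time-domain
#' features are extracted from the moving-average-smoothed signal, and the
#' fold classifier predicts each test segment. Headline numbers are the
#' mean and standard deviation of the per-fold metrics; the pooled confusion
#' matrix aggregates all folds for per-class views.
#'
#' @param study A [rehab_study()].
#' @param spec A [classifier_spec()].
#' @param segmentation `"dynamic"` (default), `"annotation"` (use the
#'   ground-truth boundaries directly), or a window spec
#'   `list(length_s =, overlap =)` for the sliding-window baseline.
#' @param maf_length Trailing moving-average window used before feature
#'   extraction (default 10 samples).
#' @param min_iou Minimum IoU for labeling detected segments (default 0.5).
#' @param alpha,beta,gamma,boundary_type Passed to
#'   [learn_segmentation_params()].
#' @return A `rehab_cv` object: per-fold metrics tibble (`folds`),
#'   mean +/- sd `aggregate`, pooled `rehab_confusion` and segment-recovery
#'   counts (`recovery`).
#' @export
loso_cv <- function(study, spec = classifier_spec(),
                    segmentation = "dynamic", maf_length = 10L,
                    min_iou = 0.5, alpha = 0.9, beta = 0.8, gamma = 1.5,
                    boundary_type = "auto") {
  stopifnot(inherits(study, "rehab_study"))
  ann <- study$annotations
  subjects <- sort(unique(ann$subject_id))
  if (length(subjects) < 2L) {
    abort("Leave-one-subject-out cross-validation needs at least 2 subjects.",
          class = "rehabrec_data_error")
  }
  rec_subject <- vapply(study$recordings, signal_subject, character(1))
  no_ann <- setdiff(unique(rec_subject), subjects)
  if (length(no_ann) > 0L) {
    abort(sprintf("Subject(s) without labeled repetitions: %s.",
                  paste(no_ann, collapse = ", ")),
          class = "rehabrec_data_error")
  }
  smoothed <- lapply(study$recordings, moving_average, length = maf_length)

  segment_set <- function(rec_ids, params) {
    dplyr::bind_rows(lapply(rec_ids, function(id) {
      if (is.character(segmentation) && segmentation == "dynamic") {
        dynamic_segment(study$recordings[[id]], params)
      } else {
        sliding_windows(study$recordings[[id]], segmentation$length_s,
                        segmentation$overlap %||% 0.5)
      }
    }))
  }

  folds <- list()
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  n_true_total <- 0L
  n_recovered_total <- 0L
  for (s in subjects) {
    train_ann <- ann[ann$subject_id != s, ]
    test_ann <- ann[ann$subject_id == s, ]
    train_ids <- unique(train_ann$recording)
    test_ids <- unique(c(test_ann$recording,
                         names(rec_subject)[rec_subject == s]))
    use_annotation <- is.character(segmentation) &&
      segmentation == "annotation"
    if (use_annotation) {
      train_lab <- train_ann
      test_lab <- dplyr::mutate(test_ann, iou = 1)
    } else {
      params <- NULL
      if (is.character(segmentation) && segmentation == "dynamic") {
        params <- learn_segmentation_params(
          study$recordings[train_ids], train_ann, alpha = alpha,
          beta = beta, gamma = gamma, boundary_type = boundary_type)
      }
      train_lab <- match_segments_to_labels(segment_set(train_ids, params),
                                            train_ann, min_iou = min_iou)
      test_lab <- match_segments_to_labels(segment_set(test_ids, params),
                                           test_ann, min_iou = min_iou)
    }
    if (nrow(test_lab) == 0L) {
      abort(sprintf(
        "No test segment of subject %s could be labeled; cannot score the fold.",
        s), class = "rehabrec_data_error")
    }
    model <- fit_classifier(featurize_dataset(smoothed, train_lab), spec)
    test_feat <- featurize_dataset(smoothed, test_lab)
    pred <- predict(model, test_feat)
    truth <- as.character(test_feat$activity)
    mets <- fold_metrics(truth, pred)
    folds[[length(folds) + 1L]] <- tibble(
      subject_id = s,
      accuracy = mets$accuracy,
      macro_recall = mets$macro_recall,
      macro_precision = mets$macro_precision,
      macro_f1 = mets$macro_f1,
      n_test = length(truth),
      n_truth = nrow(test_ann))
    pooled_truth <- c(pooled_truth, truth)
    pooled_pred <- c(pooled_pred, as.character(pred))
    n_true_total <- n_true_total + nrow(test_ann)
    n_recovered_total <- n_recovered_total + length(truth)
  }
  folds <- dplyr::bind_rows(folds)
  pooled_cm <- confusion_matrix(pooled_truth, pooled_pred)
  new_rehab_cv(folds, pooled_cm, mode = "loso", algorithm = spec$algorithm,
               recovery = list(n_truth = n_true_total,
                               n_scored = n_recovered_total))
}

#' Stratified k-fold cross-validation on a feature table
#'
#' Rows are assigned to `k` folds stratified by class under a fixed seed;
#' each row is tested exactly once. Note this mixes rows of the same subject
#' across training and test folds — use [loso_cv()] to measure
#' generalization to unseen subjects.
#'
#' @param table Feature tibble from [featurize_dataset()].
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A `rehab_cv` object (see [loso_cv()]).
#' @export
kfold_cv <- function(table, spec = classifier_spec(), k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) {
    abort("k must be an integer >= 2.", class = "rehabrec_parameter_error")
  }
  y <- as_activity(table$activity)
  class_n <- table(droplevels(y))
  if (any(class_n < k)) {
    abort(sprintf(
      "Class(es) with fewer than k = %d rows: %s. Lower k or gather more data.",
      k, paste(names(class_n)[class_n < k], collapse = ", ")),
      class = "rehabrec_data_error")
  }
  set.seed(seed)
  fold <- integer(nrow(table))
  for (cl in names(class_n)) {
    idx <- which(as.character(y) == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds <- list()
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  for (f in seq_len(k)) {
    model <- fit_classifier(table[fold != f, , drop = FALSE], spec)
    test <- table[fold == f, , drop = FALSE]
    pred <- predict(model, test)
    truth <- as.character(test$activity)
    mets <- fold_metrics(truth, pred)
    folds[[f]] <- tibble(fold = f, accuracy = mets$accuracy,
                         macro_recall = mets$macro_recall,
                         macro_precision = mets$macro_precision,
                         macro_f1 = mets$macro_f1, n_test = nrow(test))
    pooled_truth <- c(pooled_truth, truth)
    pooled_pred <- c(pooled_pred, as.character(pred))
  }
  new_rehab_cv(dplyr::bind_rows(folds),
               confusion_matrix(pooled_truth, pooled_pred),
               mode = "kfold", algorithm = spec$algorithm)
}
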