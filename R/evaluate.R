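#' Confusion matrix in canonical class order
#'
#' Rows are actual classes, columns predicted classes, both in the canonical
#' order of [activity_levels()] (restricted to `classes`). Cells may be
#' counts or non-negative weights (e.g. row percentages read from a printed
#' matrix); all derived metrics are weight-agnostic.
#'
#' @param truth,pred Vectors of activity labels of equal length `>= 1`.
#' @param classes Class order; defaults to the canonical seven labels.
#' @return A `rehab_confusion` object wrapping the K x K matrix.
#' @export
confusion_matrix <- function(truth, pred, classes = activity_levels()) {
  if (length(truth) != length(pred)) {
    abort("truth and pred must have the same length.",
          class = "rehabrec_parameter_error")
  }
  if (length(truth) == 0L) {
    abort("Cannot build a confusion matrix from zero samples.",
          class = "rehabrec_parameter_error")
  }
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  if (anyNA(truth) || anyNA(pred)) {
    abort("Labels outside the class set.", class = "rehabrec_data_error")
  }
  new_confusion(unclass(table(truth, pred)), classes)
}

new_confusion <- function(counts, classes) {
  counts <- matrix(as.numeric(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  if (any(counts < 0)) {
    abort("Confusion-matrix cells must be non-negative.",
          class = "rehabrec_data_error")
  }
  structure(list(counts = counts, classes = classes),
            class = "rehab_confusion")
}

#' @export
print.rehab_confusion <- function(x, ...) {
  cat(sprintf("# rehab_confusion: %d classes, %g samples\n",
              length(x$classes), sum(x$counts)))
  print(round(x$counts, 2))
  invisible(x)
}

#' Row-percentage view of a confusion matrix
#'
#' @param cm A `rehab_confusion`.
#' @return Matrix of row percentages (each row sums to 100; all-zero rows
#'   stay zero).
#' @export
confusion_percent <- function(cm) {
  stopifnot(inherits(cm, "rehab_confusion"))
  rs <- rowSums(cm$counts)
  rs[rs == 0] <- 1
  sweep(cm$counts, 1L, rs, "/") * 100
}

#' Recognition metrics from a confusion matrix
#'
#' Per-class recall `TP / (TP + FN)`, precision `TP / (TP + FP)` and F1
#' (harmonic mean of precision and recall), plus overall accuracy
#' (`trace / total`) and unweighted macro averages. A class that is never
#' predicted has precision 0 (with a warning), and a class with
#' `precision + recall = 0` has F1 0. Classes with no actual samples are
#' rejected. On a balanced matrix, overall accuracy equals macro recall.
#'
#' @param cm A `rehab_confusion` (from [confusion_matrix()] or
#'   [read_confusion_csv()]).
#' @return A `rehab_metrics` object: list with `per_class` tibble
#'   (`activity`, `recall`, `precision`, `f1`), `accuracy`, `macro_recall`,
#'   `macro_precision`, `macro_f1` and `n` (total weight).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "rehab_confusion"))
  counts <- cm$counts
  total <- sum(counts)
  if (total <= 0) {
    abort("Confusion matrix is empty.", class = "rehabrec_parameter_error")
  }
  actual <- rowSums(counts)
  if (any(actual == 0)) {
    abort(sprintf("Class(es) with no actual samples: %s.",
                  paste(cm$classes[actual == 0], collapse = ", ")),
          class = "rehabrec_parameter_error")
  }
  tp <- diag(counts)
  fn <- actual - tp
  fp <- colSums(counts) - tp
  recall <- tp / (tp + fn)
  never_predicted <- (tp + fp) == 0
  if (any(never_predicted)) {
    warn(sprintf("Class(es) never predicted (precision set to 0): %s.",
                 paste(cm$classes[never_predicted], collapse = ", ")))
  }
  precision <- ifelse(never_predicted, 0, tp / (tp + fp))
  pr <- precision + recall
  f1 <- ifelse(pr == 0, 0, 2 * precision * recall / pr)
  structure(list(
    per_class = tibble(activity = cm$classes, recall = unname(recall),
                       precision = unname(precision), f1 = unname(f1)),
    accuracy = sum(tp) / total,
    macro_recall = mean(recall),
    macro_precision = mean(precision),
    macro_f1 = mean(f1),
    n = total
  ), class = "rehab_metrics")
}

#' @export
print.rehab_metrics <- function(x, ...) {
  cat(sprintf(
    "# rehab_metrics: accuracy %.4f, macro recall %.4f, macro precision %.4f, macro F1 %.4f (n = %g)\n",
    x$accuracy, x$macro_recall, x$macro_precision, x$macro_f1, x$n))
  print(x$per_class)
  invisible(x)
}

#' Tidiers for rehabrec result objects
#'
#' [generics::tidy()] returns per-unit detail (per-class metrics, per-fold
#' results, classifier parameters); [generics::glance()] a one-row summary.
#'
#' @param x A rehabrec result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_rehabrec
NULL

#' @rdname tidy_rehabrec
#' @method tidy rehab_metrics
#' @export
tidy.rehab_metrics <- function(x, ...) x$per_class

#' @rdname tidy_rehabrec
#' @method glance rehab_metrics
#' @export
glance.rehab_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_recall = x$macro_recall,
         macro_precision = x$macro_precision, macro_f1 = x$macro_f1,
         n = x$n)
}

#' @rdname tidy_rehabrec
#' @method tidy rehab_confusion
#' @export
tidy.rehab_confusion <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n",
                                stringsAsFactors = FALSE))
}

#' Read and write confusion-matrix CSVs
#'
#' Dialect: first column `actual` holds the class labels; the remaining
#' columns are the predicted classes in canonical order; cells are row
#' percentages (or counts). Blank cells parse as 0.
#'
#' @param path File path.
#' @param cm A `rehab_confusion` to write.
#' @param percent Write row percentages (default) or raw counts?
#' @return `read_confusion_csv()` a `rehab_confusion`;
#'   `write_confusion_csv()` the path, invisibly.
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Confusion-matrix file does not exist: %s", path),
          class = "rehabrec_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        na = c("", "NA"))
  classes <- names(df)[-1L]
  if (!setequal(df[[1L]], classes)) {
    abort("Confusion-matrix rows and columns must list the same classes.",
          class = "rehabrec_format_error")
  }
  mat <- as.matrix(df[, -1L])
  mat[is.na(mat)] <- 0
  rownames(mat) <- df[[1L]]
  new_confusion(mat[classes, classes], classes)
}

#' @rdname read_confusion_csv
#' @export
write_confusion_csv <- function(cm, path, percent = TRUE) {
  stopifnot(inherits(cm, "rehab_confusion"))
  mat <- if (percent) confusion_percent(cm) else cm$counts
  df <- dplyr::bind_cols(tibble(actual = cm$classes),
                         as_tibble(as.data.frame(mat)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Bundled reference confusion matrices
#'
#' Row-percentage confusion matrices for the seven-exercise wrist-
#' accelerometer recognition task, as reported for the four classifier
#' configurations (SVM-RBF, KNN, random forest, naive Bayes) on a balanced
#' set of 700 repetitions (100 per class). Shipped as plain-text CSVs under
#' `inst/extdata/` and used to validate the metric arithmetic.
#'
#' @return Named list of `rehab_confusion` objects
#'   (`svm`, `knn`, `rf`, `nb`).
#' @export
#' @examples
#' glance(metrics_from_confusion(reference_confusions()$rf))
reference_confusions <- function() {
  files <- c(svm = "confusion-svm.csv", knn = "confusion-knn.csv",
             rf = "confusion-rf.csv", nb = "confusion-nb.csv")
  lapply(files, function(f) {
    read_confusion_csv(system.file("extdata", f, package = "rehabrec",
                                   mustWork = TRUE))
  })
}
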