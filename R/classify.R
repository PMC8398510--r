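#' Classifier specification
#'
#' Configuration for the four classifier families used by the pipeline.
#' Defaults follow the study configuration: an RBF-kernel SVM with
#' complexity `C = 2.0` and kernel width `gamma = 0.01` (the "radius" of the
#' RBF kernel), 1-nearest-neighbour with Euclidean distance, a 100-tree
#' random forest with `sqrt(p)` features per split, and Gaussian naive Bayes
#' with a relative variance floor so constant features cannot produce
#' degenerate likelihoods.
#'
#' @param algorithm One of `"rf"`, `"svm_rbf"`, `"knn"`, `"gnb"`.
#' @param C SVM complexity (cost) parameter.
#' @param gamma SVM RBF kernel width.
#' @param k Number of neighbours for KNN.
#' @param n_trees Number of random-forest trees.
#' @param var_floor Gaussian-NB variance floor, relative to the largest
#'   feature variance.
#' @param seed Integer seed making tree fitting deterministic.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(algorithm = c("rf", "svm_rbf", "knn", "gnb"),
                            C = 2.0, gamma = 0.01, k = 1L, n_trees = 100L,
                            var_floor = 1e-9, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(C > 0, gamma > 0, k >= 1L, n_trees >= 1L, var_floor > 0)
  structure(list(algorithm = algorithm, C = C, gamma = gamma,
                 k = as.integer(k), n_trees = as.integer(n_trees),
                 var_floor = var_floor, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$algorithm,
                  svm_rbf = sprintf("C = %g, gamma = %g", x$C, x$gamma),
                  knn = sprintf("k = %d", x$k),
                  rf = sprintf("%d trees, seed %d", x$n_trees, x$seed),
                  gnb = sprintf("variance floor %g", x$var_floor))
  cat(sprintf("# classifier_spec: %s (%s)\n", x$algorithm, extra))
  invisible(x)
}

feature_matrix <- function(table) {
  missing <- setdiff(feature_names(), names(table))
  if (length(missing) > 0L) {
    abort(sprintf("Feature table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rehabrec_data_error")
  }
  as.matrix(table[, feature_names()])
}

#' Fit a repetition classifier
#'
#' Fits the classifier described by `spec` on a feature table. Features are
#' z-score standardized with a scaler learned from these training rows only
#' (applied identically at prediction time), since RBF-SVM and KNN are
#' scale-sensitive. Training rows are first put into a canonical order
#' (label, then feature values) so that fitting — including the seeded
#' random-forest bootstrap — is invariant to the row order of the input.
#'
#' @param table Feature tibble from [featurize_dataset()] with at least two
#'   classes and no missing feature values.
#' @param spec A [classifier_spec()].
#' @return A `rehab_classifier` with a [predict()] method returning a factor
#'   of activity labels.
#' @export
fit_classifier <- function(table, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- feature_matrix(table)
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Feature table contains missing or non-finite values.",
          class = "rehabrec_data_error")
  }
  y <- as_activity(table$activity)
  y <- droplevels(y)
  if (nlevels(y) < 2L) {
    abort("Training data must contain at least two classes.",
          class = "rehabrec_data_error")
  }
  ord <- do.call(order, c(list(as.integer(y)), asplit(x, 2L)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]

  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)

  fit <- switch(spec$algorithm,
    svm_rbf = e1071::svm(xs, y, kernel = "radial", cost = spec$C,
                         gamma = spec$gamma, scale = FALSE),
    knn = list(train = xs, y = y),
    rf = {
      set.seed(spec$seed)
      randomForest::randomForest(xs, y, ntree = spec$n_trees,
                                 mtry = max(1L, floor(sqrt(ncol(xs)))))
    },
    gnb = {
      nb <- e1071::naiveBayes(as.data.frame(xs), y)
      # e1071 has no variance-floor argument: floor the per-class sds
      # relative to the largest feature variance so constant features
      # cannot yield zero-likelihood spikes.
      sd_floor <- sqrt(spec$var_floor * max(apply(xs, 2L, stats::var), 1e-12))
      nb$tables <- lapply(nb$tables, function(tb) {
        tb[, 2L] <- pmax(tb[, 2L], sd_floor)
        tb
      })
      nb
    })

  structure(list(spec = spec, fit = fit, center = center, scale = scale_,
                 classes = levels(y)),
            class = "rehab_classifier")
}

#' @export
print.rehab_classifier <- function(x, ...) {
  cat(sprintf("# rehab_classifier: %s over %d classes (%s)\n",
              x$spec$algorithm, length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict activity labels
#'
#' @param object A `rehab_classifier` from [fit_classifier()].
#' @param newdata Feature tibble with the 24 columns of [feature_names()].
#' @param ... Unused.
#' @return Factor of predicted labels with levels [activity_levels()]; empty
#'   input yields an empty factor.
#' @export
predict.rehab_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (nrow(x) == 0L) return(factor(character(0), levels = activity_levels()))
  xs <- scale(x, center = object$center, scale = object$scale)
  pred <- switch(object$spec$algorithm,
    svm_rbf = predict(object$fit, xs),
    knn = class::knn(object$fit$train, xs, object$fit$y, k = object$spec$k),
    rf = predict(object$fit, xs),
    gnb = predict(object$fit, as.data.frame(xs)))
  factor(as.character(pred), levels = activity_levels())
}

#' @rdname tidy_rehabrec
#' @method tidy rehab_classifier
#' @export
tidy.rehab_classifier <- function(x, ...) {
  tibble(algorithm = x$spec$algorithm,
         parameter = c("C", "gamma", "k", "n_trees", "seed"),
         value = c(x$spec$C, x$spec$gamma, x$spec$k, x$spec$n_trees,
                   x$spec$seed))
}
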