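#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one list. Either
#' `simulate = TRUE` (generate a synthetic study from `design`) or
#' `recordings_dir` + `annotations` must be supplied.
#'
#' @param simulate Generate the input study synthetically?
#' @param design A [study_design()] used when `simulate = TRUE`.
#' @param recordings_dir Directory of recording CSVs (one per recording,
#'   named `<subject>_<activity>.csv`), used when `simulate = FALSE`.
#' @param annotations Path to the annotation CSV.
#' @param output_dir Where artifacts are written (`NULL` = nowhere).
#' @param maf_length Moving-average window for feature extraction.
#' @param segmentation `"dynamic"`, `"annotation"`, or a window spec list.
#' @param alpha,beta,gamma,boundary_type Segmentation-learning settings.
#' @param min_iou Segment-labeling IoU threshold.
#' @param classifier A [classifier_spec()].
#' @param cv `"loso"` or `"kfold"`.
#' @param k Folds for `cv = "kfold"`.
#' @param seed Seed recorded in reports and used for k-fold assignment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, design = study_design(),
                            recordings_dir = NULL, annotations = NULL,
                            output_dir = NULL, maf_length = 10L,
                            segmentation = "dynamic", alpha = 0.9,
                            beta = 0.8, gamma = 1.5,
                            boundary_type = "auto", min_iou = 0.5,
                            classifier = classifier_spec(), cv = "loso",
                            k = 10L, seed = 42L) {
  structure(list(simulate = simulate, design = design,
                 recordings_dir = recordings_dir,
                 annotations = annotations, output_dir = output_dir,
                 maf_length = maf_length, segmentation = segmentation,
                 alpha = alpha, beta = beta, gamma = gamma,
                 boundary_type = boundary_type, min_iou = min_iou,
                 classifier = classifier, cv = cv, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_study_from_config <- function(config) {
  if (isTRUE(config$simulate)) {
    return(simulate_study(config$design))
  }
  if (is.null(config$recordings_dir) || !dir.exists(config$recordings_dir)) {
    abort(sprintf("Recordings directory does not exist: %s",
                  config$recordings_dir %||% "<unset>"),
          class = "rehabrec_io_error")
  }
  ann <- read_annotations(config$annotations)
  files <- list.files(config$recordings_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  files <- files[normalizePath(files, mustWork = FALSE) !=
                   normalizePath(config$annotations, mustWork = FALSE)]
  recordings <- list()
  for (f in files) {
    rec_id <- sub("\\.csv$", "", basename(f))
    sid <- ann$subject_id[match(rec_id, ann$recording)]
    recordings[[rec_id]] <- read_recording(f, subject_id = sid,
                                           recording_id = rec_id)
  }
  rehab_study(recordings, ann)
}

#' Run the full recognition pipeline
#'
#' Executes preprocess -> segment -> label -> featurize -> cross-validated
#' evaluation under one [pipeline_config()], optionally writing a metrics
#' CSV (per fold plus aggregate), the pooled confusion matrix CSV and a
#' plain-text report recording the seed and a configuration hash, so a rerun
#' with the same configuration reproduces the files.
#'
#' @param config A [pipeline_config()].
#' @return The `rehab_cv` result, invisibly when `output_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- load_study_from_config(config)
  cv <- if (config$cv == "kfold") {
    smoothed <- lapply(study$recordings, moving_average,
                       length = config$maf_length)
    kfold_cv(featurize_dataset(smoothed, study$annotations),
             config$classifier, k = config$k, seed = config$seed)
  } else {
    loso_cv(study, config$classifier, segmentation = config$segmentation,
            maf_length = config$maf_length, min_iou = config$min_iou,
            alpha = config$alpha, beta = config$beta, gamma = config$gamma,
            boundary_type = config$boundary_type)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    fold_rows <- dplyr::mutate(tidy(cv), unit = "fold", .before = 1L)
    agg <- cv$aggregate
    readr::write_csv(fold_rows, file.path(config$output_dir, "metrics_folds.csv"),
                     progress = FALSE)
    readr::write_csv(agg, file.path(config$output_dir, "metrics_aggregate.csv"),
                     progress = FALSE)
    write_confusion_csv(cv$pooled,
                        file.path(config$output_dir, "confusion_pooled.csv"))
    cfg_hash <- rlang::hash(config)
    writeLines(c(
      sprintf("rehabrec pipeline report"),
      sprintf("config_hash: %s", cfg_hash),
      sprintf("seed: %d", config$seed),
      sprintf("cv: %s", config$cv),
      sprintf("classifier: %s", config$classifier$algorithm),
      sprintf("segmentation: %s",
              if (is.character(config$segmentation)) config$segmentation
              else sprintf("window_%gs", config$segmentation$length_s)),
      sprintf("accuracy_mean: %.6f", agg$mean[agg$metric == "accuracy"]),
      sprintf("macro_f1_mean: %.6f", agg$mean[agg$metric == "macro_f1"])
    ), file.path(config$output_dir, "report.txt"))
    return(invisible(cv))
  }
  cv
}

#' Compare dynamic segmentation against sliding windows
#'
#' Runs the identical downstream pipeline (labeling, features, classifier,
#' leave-one-subject-out evaluation) under four segmentation regimes —
#' dynamic, and fixed sliding windows of the given lengths at 50% overlap —
#' and tabulates per-activity F1 (from the pooled confusion matrix) plus
#' overall accuracy for each regime.
#'
#' @param study A [rehab_study()].
#' @param spec A [classifier_spec()].
#' @param window_lengths_s Sliding-window lengths in seconds
#'   (default `c(2, 2.5, 3.5)`).
#' @param overlap Window overlap fraction (default 0.5).
#' @param maf_length,min_iou,alpha,beta,gamma,boundary_type As in
#'   [loso_cv()].
#' @return A `segmentation_comparison` tibble: one row per regime with
#'   per-activity F1 columns, `overall_accuracy` (pooled) and
#'   `accuracy_mean` (across folds); the full `rehab_cv` objects are
#'   attached as the `"cv"` attribute.
#' @export
compare_segmentation <- function(study, spec = classifier_spec(),
                                 window_lengths_s = c(2, 2.5, 3.5),
                                 overlap = 0.5, maf_length = 10L,
                                 min_iou = 0.5, alpha = 0.9, beta = 0.8,
                                 gamma = 1.5, boundary_type = "auto") {
  regimes <- c(list(dynamic = "dynamic"),
               setNames(lapply(window_lengths_s,
                               function(l) list(length_s = l,
                                                overlap = overlap)),
                        sprintf("window_%gs", window_lengths_s)))
  cvs <- lapply(regimes, function(seg) {
    loso_cv(study, spec, segmentation = seg, maf_length = maf_length,
            min_iou = min_iou, alpha = alpha, beta = beta, gamma = gamma,
            boundary_type = boundary_type)
  })
  rows <- purrr::imap(cvs, function(cv, name) {
    counts <- cv$pooled$counts
    f1 <- setNames(rep(NA_real_, length(activity_levels())),
                   activity_levels())
    present <- activity_levels()[rowSums(counts) > 0]
    sub <- new_confusion(counts[present, present, drop = FALSE], present)
    mets <- withCallingHandlers(
      metrics_from_confusion(sub),
      warning = function(w) invokeRestart("muffleWarning"))
    f1[mets$per_class$activity] <- mets$per_class$f1
    dplyr::bind_cols(
      tibble(regime = name),
      as_tibble(as.list(f1)),
      tibble(overall_accuracy = sum(diag(counts)) / sum(counts),
             accuracy_mean = mean(cv$folds$accuracy),
             n_scored = sum(counts)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cv") <- cvs
  class(out) <- c("segmentation_comparison", class(out))
  out
}
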