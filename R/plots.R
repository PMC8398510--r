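#' Plot an acceleration signal
#'
#' Facetted line plot of the three axes (and optionally the magnitude) over
#' time, with detected or annotated segments shaded if supplied.
#'
#' @param object An [accel_signal()].
#' @param segments Optional segment tibble (`start`, `end`, optionally
#'   `activity`) to shade.
#' @param magnitude Add the magnitude channel as a fourth facet?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accel_signal
#' @export
autoplot.accel_signal <- function(object, segments = NULL,
                                  magnitude = FALSE, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("x_g", "y_g", "z_g"),
                            names_to = "channel", values_to = "g")
  if (magnitude) {
    df <- dplyr::bind_rows(df, tibble(time_s = object$time_s,
                                      channel = "m_g",
                                      g = signal_magnitude(object)))
  }
  df$channel <- factor(df$channel, levels = c("x_g", "y_g", "z_g", "m_g"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)",
                  title = sprintf("subject %s, recording %s",
                                  signal_subject(object),
                                  signal_recording(object)))
  if (!is.null(segments) && nrow(segments) > 0L) {
    fs <- signal_fs(object)
    shade <- tibble(xmin = (segments$start - 1) / fs,
                    xmax = segments$end / fs)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Plot a confusion matrix
#'
#' Heat-map of row percentages with cell labels, rows = actual and
#' columns = predicted activity in canonical order.
#'
#' @param object A `rehab_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rehab_confusion
#' @export
autoplot.rehab_confusion <- function(object, ...) {
  pct <- confusion_percent(object)
  df <- as_tibble(as.data.frame.table(pct, responseName = "percent",
                                      stringsAsFactors = FALSE))
  df$actual <- factor(df$actual, levels = rev(object$classes))
  df$predicted <- factor(df$predicted, levels = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$percent == 0, "",
                     formatC(.data$percent, digits = 1, format = "f"))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predicted activity", y = "actual activity",
                  fill = "% of row")
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold and metric, with the aggregate mean +/- sd overlaid.
#'
#' @param object A `rehab_cv` from [loso_cv()] or [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rehab_cv
#' @export
autoplot.rehab_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds,
    c("accuracy", "macro_recall", "macro_precision", "macro_f1"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%s cross-validation (%s)", object$mode,
                                  object$algorithm))
}

#' Plot a segmentation-regime comparison
#'
#' Per-activity F1 by segmentation regime, as produced by
#' [compare_segmentation()].
#'
#' @param object A `segmentation_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segmentation_comparison
#' @export
autoplot.segmentation_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::all_of(activity_levels()),
                              names_to = "activity", values_to = "f1")
  long$activity <- factor(long$activity, levels = activity_levels())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$activity, y = .data$f1,
                                     fill = .data$regime)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "F1 (pooled)", fill = "segmentation")
}
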