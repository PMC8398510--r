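#' Canonical activity labels
#'
#' The seven upper-limb rehabilitation exercises recognized by the pipeline,
#' in the fixed order used for every confusion matrix and factor level set:
#' shoulder abduction (SA), elbow extension (EE), elbow flexion (EF),
#' shoulder external rotation (SER), shoulder internal rotation (SIR),
#' shoulder extension (SE) and shoulder flexion (SF).
#'
#' @return Character vector of the seven activity codes in canonical order.
#' @export
#' @examples
#' activity_levels()
activity_levels <- function() {
  c("SA", "EE", "EF", "SER", "SIR", "SE", "SF")
}

#' Coerce to the canonical activity factor
#'
#' @param x Character or factor of activity codes.
#' @param allow_unlabeled Accept `"?"` (used for not-yet-labeled segments)?
#' @return Factor with levels [activity_levels()].
#' @export
as_activity <- function(x, allow_unlabeled = FALSE) {
  x <- as.character(x)
  ok <- x %in% activity_levels() | (allow_unlabeled & x == "?")
  if (!all(ok)) {
    abort(sprintf(
      "Unknown activity code(s): %s. Valid codes: %s.",
      paste(unique(x[!ok]), collapse = ", "),
      paste(activity_levels(), collapse = ", ")
    ), class = "rehabrec_data_error")
  }
  factor(x, levels = if (allow_unlabeled) c(activity_levels(), "?") else activity_levels())
}
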