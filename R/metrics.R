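#' Segmentation evaluation metrics
#'
#' `dice()` computes the Dice coefficient `2|P intersect M| / (|P| + |M|)`
#' between a predicted region P and a ground-truth region M; `sensitivity()`
#' the fraction of ground-truth positives correctly predicted (`TP / P`);
#' `specificity()` the fraction of ground-truth negatives correctly
#' predicted (`TN / N`). Probability maps are thresholded first. Edge cases:
#' Dice of two empty regions is defined as 1; sensitivity (specificity) is
#' `NA` — an explicit undefined marker — when the ground truth has no
#' positives (negatives).
#'
#' @param prediction binary mask or probability map in `[0, 1]` (matrix or
#'   array).
#' @param truth binary ground-truth mask of identical dimensions.
#' @param threshold probability threshold applied to `prediction`.
#' @return scalar in `[0, 1]`, or `NA` where undefined.
#' @export
dice <- function(prediction, truth, threshold = 0.5) {
  cm <- confusion_counts(prediction, truth, threshold)
  if (cm["tp"] + cm["fp"] + cm["fn"] == 0) return(1)
  unname(2 * cm["tp"] / (2 * cm["tp"] + cm["fp"] + cm["fn"]))
}

#' @rdname dice
#' @export
sensitivity <- function(prediction, truth, threshold = 0.5) {
  cm <- confusion_counts(prediction, truth, threshold)
  pos <- cm["tp"] + cm["fn"]
  if (pos == 0) return(NA_real_)
  unname(cm["tp"] / pos)
}

#' @rdname dice
#' @export
specificity <- function(prediction, truth, threshold = 0.5) {
  cm <- confusion_counts(prediction, truth, threshold)
  neg <- cm["tn"] + cm["fp"]
  if (neg == 0) return(NA_real_)
  unname(cm["tn"] / neg)
}

confusion_counts <- function(prediction, truth, threshold = 0.5) {
  if (!identical(dim2(prediction), dim2(truth)))
    stop("prediction and ground truth must have identical dimensions")
  t <- as.numeric(truth)
  if (!all(t %in% c(0, 1)))
    stop("ground-truth mask must be strictly binary")
  p <- as.numeric(prediction) > threshold
  t <- t > 0.5
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
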