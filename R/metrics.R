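# Overlap metrics for segmentation masks: confusion counts, Dice similarity
# coefficient, intersection over union, precision and recall, plus one-vs-rest
# per-class reporting with macro averaging.
#
# Conventions: with TP/FP/FN/TN the voxel tallies of a predicted mask P1
# against a ground-truth mask P2,
#   DSC       = 2|P1 n P2| / (|P1| + |P2|)
#   IoU       = TP / (TP + FN + FP)
#   Precision = TP / (TP + FP)
#   Recall    = TP / (TP + FN)
# Degenerate denominators (both masks empty, or no predicted/true positives
# for precision/recall) are scored 1: an empty prediction of an empty truth
# is vacuously perfect.

#' Confusion counts for a mask pair
#'
#' @param pred,truth Binary arrays (0/1) on the same grid.
#' @return A list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("mask extents differ", call. = FALSE)
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  tp <- sum(p & t)
  list(tp = tp, fp = sum(p) - tp, fn = sum(t) - tp,
       tn = sum(!p & !t))
}

#' Dice similarity coefficient
#'
#' @inheritParams confusion_counts
#' @return DSC in `[0, 1]`; 1 when both masks are empty.
#' @export
dice <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) 1 else 2 * cc$tp / denom
}

#' Intersection over union
#'
#' @param counts Confusion counts from [confusion_counts()], or a binary
#'   mask (then `truth` must be given).
#' @param truth Optional ground-truth mask.
#' @return IoU in `[0, 1]`; 1 when TP+FP+FN is zero.
#' @export
iou <- function(counts, truth = NULL) {
  cc <- if (!is.null(truth)) confusion_counts(counts, truth) else counts
  denom <- cc$tp + cc$fn + cc$fp
  if (denom == 0) 1 else cc$tp / denom
}

#' Precision
#'
#' @inheritParams iou
#' @return TP / (TP + FP); 1 when no positives are predicted.
#' @export
precision <- function(counts, truth = NULL) {
  cc <- if (!is.null(truth)) confusion_counts(counts, truth) else counts
  denom <- cc$tp + cc$fp
  if (denom == 0) 1 else cc$tp / denom
}

#' Recall
#'
#' @inheritParams iou
#' @return TP / (TP + FN); 1 when the truth has no positives.
#' @export
recall <- function(counts, truth = NULL) {
  cc <- if (!is.null(truth)) confusion_counts(counts, truth) else counts
  denom <- cc$tp + cc$fn
  if (denom == 0) 1 else cc$tp / denom
}

#' Per-class and macro metric report
#'
#' One-vs-rest DSC, IoU, precision and recall per class, reported as
#' percentages rounded to two decimals. The macro row averages over the
#' classes present in the ground truth (per-scan vertebra subsets vary, so
#' absent classes are flagged and excluded from the macro mean).
#'
#' @param pred,truth Integer label arrays on the same grid.
#' @param classes Integer labels to report (default: all nonzero labels in
#'   truth or prediction).
#' @return A tibble with columns `class`, `present`, `dsc_pct`, `iou_pct`,
#'   `precision_pct`, `recall_pct`, plus a final `macro` row averaging the
#'   classes present in the truth.
#' @export
macro_report <- function(pred, truth, classes = NULL) {
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and truth are misaligned", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(c(as.integer(pred), as.integer(truth))), 0))
  }
  rows <- lapply(classes, function(k) {
    cc <- confusion_counts(pred == k, truth == k)
    in_truth <- (cc$tp + cc$fn) > 0
    d <- if (cc$tp + cc$fp + cc$fn == 0) 1 else
      2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
    tibble::tibble(class = as.character(k),
                   present = in_truth,
                   dsc_pct = 100 * d,
                   iou_pct = 100 * iou(cc),
                   precision_pct = 100 * precision(cc),
                   recall_pct = 100 * recall(cc))
  })
  tab <- do.call(rbind, rows)
  pres <- tab[tab$present, , drop = FALSE]
  macro <- tibble::tibble(
    class = "macro", present = TRUE,
    dsc_pct = mean(pres$dsc_pct),
    iou_pct = mean(pres$iou_pct),
    precision_pct = mean(pres$precision_pct),
    recall_pct = mean(pres$recall_pct)
  )
  out <- rbind(tab, macro)
  out$dsc_pct <- round(out$dsc_pct, 2)
  out$iou_pct <- round(out$iou_pct, 2)
  out$precision_pct <- round(out$precision_pct, 2)
  out$recall_pct <- round(out$recall_pct, 2)
  out
}
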