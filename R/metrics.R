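# Confusion-matrix based binary segmentation metrics.
#
# Dataset-level scores pool pixel counts over all images before computing the
# ratios (per-image averaging is also available in evaluate_model); the
# binarization threshold applies with >= at the boundary.

#' Pixel confusion matrix
#'
#' @param pred probability (or binary) map.
#' @param truth binary ground-truth mask of the same shape, values in {0, 1}.
#' @param threshold a pixel counts as predicted-positive iff
#'   `pred >= threshold`.
#' @return a `confusion_matrix` list with integer counts TP, FP, FN, TN.
#' @export
confusion <- function(pred, truth, threshold = 0.5) {
  if (!identical(dim_of(pred), dim_of(truth)))
    stop("pred and truth must have identical shapes")
  tv <- as.numeric(truth)
  if (!all(tv %in% c(0, 1))) stop("truth mask must be strictly binary")
  pp <- as.numeric(pred) >= threshold
  tp <- sum(pp & tv == 1)
  fp <- sum(pp & tv == 0)
  fn <- sum(!pp & tv == 1)
  tn <- sum(!pp & tv == 0)
  new_confusion(tp, fp, fn, tn)
}

new_confusion <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  cm <- list(TP = tp, FP = fp, FN = fn, TN = tn)
  class(cm) <- "confusion_matrix"
  cm
}

#' Sum confusion matrices (pixel pooling)
#' @param ... `confusion_matrix` objects.
#' @return their elementwise sum.
#' @export
cm_sum <- function(...) {
  cms <- list(...)
  if (length(cms) == 1L && is.list(cms[[1]]) && !inherits(cms[[1]], "confusion_matrix"))
    cms <- cms[[1]]
  new_confusion(sum(vapply(cms, `[[`, numeric(1), "TP")),
                sum(vapply(cms, `[[`, numeric(1), "FP")),
                sum(vapply(cms, `[[`, numeric(1), "FN")),
                sum(vapply(cms, `[[`, numeric(1), "TN")))
}

#' Pixel accuracy: (TP + TN) / total
#' @param cm a `confusion_matrix`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total == 0) stop("accuracy undefined: empty confusion matrix")
  (cm$TP + cm$TN) / total
}

#' Mean intersection over union
#'
#' Mean of foreground IoU `TP/(TP+FP+FN)` and background IoU
#' `TN/(TN+FN+FP)`. A class absent from both prediction and truth has IoU 1
#' (nothing to miss); absent from truth but predicted (or vice versa) gives 0.
#'
#' @param cm a `confusion_matrix`.
#' @return mIoU in `[0, 1]`.
#' @export
miou <- function(cm) {
  iou_fg <- if (cm$TP + cm$FP + cm$FN == 0) 1 else cm$TP / (cm$TP + cm$FP + cm$FN)
  iou_bg <- if (cm$TN + cm$FN + cm$FP == 0) 1 else cm$TN / (cm$TN + cm$FN + cm$FP)
  (iou_fg + iou_bg) / 2
}

#' Recall: TP / (TP + FN)
#' @param cm a `confusion_matrix`.
#' @return recall in `[0, 1]`.
#' @export
recall <- function(cm) {
  if (cm$TP + cm$FN == 0)
    stop("recall undefined: no positive pixels in the ground truth")
  cm$TP / (cm$TP + cm$FN)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Write a metric report file
#'
#' JSON with keys `miou`, `acc`, `recall` as percentages rounded to two
#' decimals (table style), plus the raw proportions under `raw`.
#'
#' @param metrics named list with elements `miou`, `acc`, `recall` in `[0,1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(metrics, path) {
  out <- list(miou = round(100 * metrics$miou, 2),
              acc = round(100 * metrics$acc, 2),
              recall = round(100 * metrics$recall, 2),
              raw = metrics[c("miou", "acc", "recall")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
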