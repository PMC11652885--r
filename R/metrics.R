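# Virtual-screen evaluation: confusion counts, sensitivity, specificity and
# the power metric PM = TPR / (TPR + FPR).

#' Confusion counts from per-compound predictions and truth
#'
#' @param predictions named logical vector (names are compound ids).
#' @param truth named logical vector over the same compound set.
#' @return list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predictions, truth) {
  if (is.null(names(predictions)) || is.null(names(truth))) {
    stop("predictions and truth must be named by compound id")
  }
  extra <- setdiff(names(predictions), names(truth))
  missing <- setdiff(names(truth), names(predictions))
  if (length(extra) + length(missing) > 0) {
    stop("compound sets differ; only in predictions: {",
         paste(extra, collapse = ", "), "}; only in truth: {",
         paste(missing, collapse = ", "), "}")
  }
  truth <- truth[names(predictions)]
  structure(list(
    tp = sum(predictions & truth),
    fp = sum(predictions & !truth),
    tn = sum(!predictions & !truth),
    fn = sum(!predictions & truth)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP=", x$tp, " FP=", x$fp, " TN=", x$tn, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

# round-half-up at 2 decimals, matching how the campaign reported metrics
round2_half_up <- function(x) floor(x * 100 + 0.5) / 100

#' Screen evaluation metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the power metric
#' `PM = TPR/(TPR+FPR)`. PM lies in `[0, 1]`; 0.5 marks a random screen and
#' PM = 1 holds iff FPR = 0 with TPR > 0. When TPR = FPR = 0 the PM is
#' defined as 0 with a warning (a screen that retains nothing is useless).
#'
#' @param counts `confusion_counts` (or a list with `tp`, `fp`, `tn`, `fn`).
#' @return list of class `screen_metrics` with full-precision values plus
#'   `rounded` (2-decimal, half-up) for comparison with printed tables.
#' @export
screen_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  if (tp + fn == 0) stop("no positives in truth: sensitivity undefined")
  if (tn + fp == 0) stop("no negatives in truth: specificity undefined")
  tpr <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  pm <- if (tpr + fpr == 0) {
    warning("TPR = FPR = 0; defining PM = 0")
    0
  } else {
    tpr / (tpr + fpr)
  }
  out <- list(sensitivity = tpr, specificity = tn / (tn + fp),
              power_metric = pm, tpr = tpr, fpr = fpr)
  out$rounded <- lapply(out, round2_half_up)
  structure(out, class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.2f | specificity %.2f | power metric %.2f\n",
    x$rounded$sensitivity, x$rounded$specificity, x$rounded$power_metric))
  invisible(x)
}
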