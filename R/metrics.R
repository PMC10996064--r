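#' Classification performance metrics from labels
#'
#' Computes accuracy, sensitivity, specificity (all in percent), precision
#' and F1 score (proportions) from true and predicted binary labels, with
#' `"positive"` as the positive class.
#'
#' @param truth,pred Factors or characters with values `negative`/`positive`.
#' @return Named list with `tp`, `fn`, `tn`, `fp`, `accuracy`, `sensitivity`,
#'   `specificity` (percent), `precision`, `f1` (proportions).
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% c("negative", "positive")),
            all(pred %in% c("negative", "positive")))
  tp <- sum(truth == "positive" & pred == "positive")
  fn <- sum(truth == "positive" & pred == "negative")
  tn <- sum(truth == "negative" & pred == "negative")
  fp <- sum(truth == "negative" & pred == "positive")
  metrics_from_confusion(tp, fn, tn, fp)
}

#' Classification performance metrics from confusion counts
#'
#' Pure metric arithmetic: accuracy = (TP+TN)/n, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP) (percent); precision = TP/(TP+FP) and
#' F1 = 2*precision*sensitivity/(precision+sensitivity) (proportions).
#' Undefined ratios (zero denominators) are returned as `NaN`.
#'
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @return Named list as in [confusion_metrics()].
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  stopifnot(n > 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  f1 <- 2 * prec * sens / (prec + sens)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = 100 * (tp + tn) / n,
       sensitivity = 100 * sens,
       specificity = 100 * spec,
       precision = prec,
       f1 = f1)
}

#' Area under the ROC curve (rank form)
#'
#' Mann-Whitney formulation: the AUC is the probability that a random
#' positive scores above a random negative, with ties counted half. Computed
#' from the rank sum of the positive-class scores; equivalent to trapezoidal
#' integration of the ROC curve.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param truth Labels `negative`/`positive`.
#' @return AUC in 0..1.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == "positive"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
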