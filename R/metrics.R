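#' Classification metrics from labels and scores
#'
#' Confusion-matrix metrics at a decision threshold (scores `>= threshold`
#' are called positive) plus the AUC computed by the rank (Mann-Whitney)
#' statistic, with tied scores receiving half credit. When only one class is
#' present the AUC is undefined and returned as `NA` with a warning.
#'
#' @param y_true Binary labels (0/1).
#' @param scores Predicted positive-class probabilities in \[0, 1\].
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `specificity`, `sensitivity`, `f1`, `auc`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  tn <- sum(pred == 0 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warn("compute_metrics: only one class present; AUC is undefined")
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(y_true),
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    auc = auc
  )
}

#' Points of the empirical ROC curve
#'
#' @param y_true Binary labels.
#' @param scores Predicted scores.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = if (n0 > 0) sum(pred & y_true == 0) / n0 else NA_real_,
           tpr = if (n1 > 0) sum(pred & y_true == 1) / n1 else NA_real_)
  })
}
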