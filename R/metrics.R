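# Confusion-matrix and ranking metrics for the binary classifier:
# accuracy, precision, recall, ROC AUC (rank statistic, ties counted 1/2)
# and mean binary cross-entropy.

.check_probs <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) {
    abort("y_true and y_prob must have equal length")
  }
  if (!length(y_true)) abort("need at least one sample")
  if (anyNA(y_prob) || any(y_prob < 0 | y_prob > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (!all(y_true %in% c(0, 1))) abort("labels must be 0/1")
}

#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive iff its probability is `>= threshold`.
#'
#' @param y_true 0/1 labels (1 = diseased).
#' @param y_prob Predicted probabilities in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return A `confusion_counts` one-row tibble with `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(.9, .2, .8, .1))
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  .check_probs(y_true, y_prob)
  pred <- y_prob >= threshold
  out <- tibble(
    TP = sum(pred & y_true == 1),
    FP = sum(pred & y_true == 0),
    TN = sum(!pred & y_true == 0),
    FN = sum(!pred & y_true == 1)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted one half -- the exact area under the
#' empirical ROC curve traced over all thresholds. Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Scores (need not be probabilities for the AUC itself).
#' @return AUC in `[0, 1]`, or `NA` when either class is absent.
#' @export
auc_roc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean binary cross-entropy (nats per sample)
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[eps, 1 - eps]`.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Predicted probabilities.
#' @param eps Clipping constant.
#' @return Non-negative scalar loss.
#' @examples
#' bce(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bce <- function(y_true, y_prob, eps = 1e-7) {
  .check_probs(y_true, y_prob)
  p <- pmin(pmax(y_prob, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Full evaluation metric suite
#'
#' Accuracy, precision, recall (from the thresholded confusion counts), ROC
#' AUC and mean binary cross-entropy. Ratios with a zero denominator are
#' reported as `NA`, never silently as zero.
#'
#' @inheritParams confusion
#' @return A `metrics_report` one-row tibble: `accuracy`, `auc`,
#'   `precision`, `recall`, `bce_loss`, plus the four confusion counts.
#' @export
metric_suite <- function(y_true, y_prob, threshold = 0.5) {
  cm <- confusion(y_true, y_prob, threshold)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble(
    accuracy = ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN),
    auc = auc_roc(y_true, y_prob),
    precision = ratio(cm$TP, cm$TP + cm$FP),
    recall = ratio(cm$TP, cm$TP + cm$FN),
    bce_loss = bce(y_true, y_prob),
    TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN
  )
  class(out) <- c("metrics_report", class(out))
  out
}
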