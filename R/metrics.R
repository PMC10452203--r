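#' ROC-AUC via rank statistics
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted half: computed from the Mann-Whitney
#' statistic on midranks, so it is invariant to any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels; 1 is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes required for ROC-AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision and recall at a fixed threshold
#'
#' Positive class is PD (= 1); a sample is called positive when its score
#' strictly exceeds the threshold. If nothing is called positive,
#' precision is reported as 0 with a warning.
#'
#' @param scores Numeric probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L) {
    stop("positive class absent", call. = FALSE)
  }
  pred <- scores > threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  precision <- if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0", call. = FALSE)
    0
  } else tp / (tp + fp)
  c(precision = precision, recall = tp / (tp + fn))
}
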