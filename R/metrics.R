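#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half — identical to the
#' trapezoidal area under the empirical ROC curve. Computed from midranks.
#'
#' @param labels Binary labels (1 = positive / non-survivor).
#' @param probabilities Scores; any monotone transform gives the same AUC.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities)) stop("length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("AUC undefined: single-class labels")
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity and specificity at a probability cutoff
#'
#' Predictions strictly greater than `cutoff` are classified positive
#' (non-survivor). Sensitivity = TP / (TP + FN) over true positives,
#' specificity = TN / (TN + FP) over true negatives.
#'
#' @param labels Binary labels (1 = positive).
#' @param probabilities Predicted probabilities.
#' @param cutoff Decision threshold (default 0.5).
#' @return Named vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec <- function(labels, probabilities, cutoff = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probabilities > cutoff)
  pos <- labels == 1L
  c(
    sensitivity = if (any(pos)) mean(pred[pos] == 1L) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] == 0L) else NA_real_
  )
}

#' Youden's J statistic at a cutoff
#'
#' J = sensitivity + specificity - 1; ranges over [-1, 1], equals 0 for any
#' classification rule that ignores the data (e.g. always-negative).
#'
#' @inheritParams sens_spec
#' @return Scalar J.
#' @export
youden_j <- function(labels, probabilities, cutoff = 0.5) {
  ss <- sens_spec(labels, probabilities, cutoff = cutoff)
  unname(ss[1] + ss[2] - 1)
}
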