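#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with half credit for ties. Computed from
#' midranks, so it agrees exactly with the brute-force pairwise estimator.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary vector.
#' @return A number in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("lengths differ")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks give the tie convention
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with step interpolation:
#' `sum_k (R_k - R_{k-1}) P_k` over descending-score thresholds (one
#' threshold per distinct score). Trapezoidal interpolation of the PR curve
#' is deliberately not used, as it overestimates the area.
#'
#' @inheritParams auroc
#' @return A number in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("lengths differ")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("AUPRC undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # evaluate only at the last index of each tied score block
  last <- which(c(s[-1L] != s[-length(s)], TRUE))
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and binary outcomes,
#' `(1/n) sum (p - y)^2`. A proper scoring rule: lower means better
#' calibrated (0 is perfect, 0.25 is the uninformative constant 0.5).
#'
#' @param probabilities predicted probabilities.
#' @param labels binary vector of the same length.
#' @return A number in `[0, 1]`.
#' @export
brier_score <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) stop("lengths differ")
  mean((probabilities - as.numeric(labels))^2)
}

#' Reliability curve (calibration bins)
#'
#' Assigns probabilities to `n_bins` equal-width bins over `[0, 1]` (right
#' closed, first bin also closed at 0) and reports, per nonempty bin, the
#' mean predicted probability and the empirical fraction of positives. For a
#' calibrated model the two track each other (the diagonal of a reliability
#' diagram).
#'
#' @inheritParams brier_score
#' @param n_bins number of bins (default 10).
#' @return Data frame with columns `bin`, `lower`, `upper`, `mean_predicted`,
#'   `fraction_positive`, `count`; empty bins are omitted, and counts sum to
#'   the number of scored pairs.
#' @export
reliability_curve <- function(probabilities, labels, n_bins = 10L) {
  if (length(probabilities) != length(labels)) stop("lengths differ")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(probabilities, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  keep <- sort(unique(bin))  # tapply/table results align with this order
  data.frame(
    bin = keep,
    lower = breaks[keep],
    upper = breaks[keep + 1L],
    mean_predicted = as.numeric(tapply(probabilities, bin, mean)),
    fraction_positive = as.numeric(tapply(as.numeric(labels), bin, mean)),
    count = as.integer(table(bin))
  )
}

#' Full evaluation report for a scored edge set
#'
#' Bundles the ranking metrics (AUPRC, AUROC), the calibration summary
#' (Brier score) and the reliability table for one set of scored pairs.
#'
#' @inheritParams brier_score
#' @param n_bins reliability bins.
#' @return An object of class `eval_report` with elements `auprc`, `auroc`,
#'   `brier`, `n` and `reliability`.
#' @export
eval_report <- function(probabilities, labels, n_bins = 10L) {
  structure(
    list(auprc = auprc(probabilities, labels),
         auroc = auroc(probabilities, labels),
         brier = brier_score(probabilities, labels),
         n = length(labels),
         reliability = reliability_curve(probabilities, labels, n_bins)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d pairs: AUPRC %.4f  AUROC %.4f  Brier %.4f\n",
              x$n, x$auprc, x$auroc, x$brier))
  invisible(x)
}
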