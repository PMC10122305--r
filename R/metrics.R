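#' Area under the precision-recall curve (average precision)
#'
#' Computed as the step-wise sum of precision times recall increments over
#' descending unique score thresholds (average precision, not trapezoidal
#' interpolation — the two differ on small sets). Tied scores are grouped at
#' a single threshold. AUPR is the headline metric here because the pair
#' labels are highly unbalanced: its baseline is the positive prevalence,
#' not 0.5.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric score vector of equal length.
#' @return Area in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  check_two_classes(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores: keep only the last index of each tie group
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab)[last]
  n_at <- seq_along(lab)[last]
  precision <- tp / n_at
  d_tp <- diff(c(0, tp))
  sum(precision * d_tp) / sum(labels)
}

#' Area under the ROC curve
#'
#' Equals the normalised Mann-Whitney U statistic: the probability that a
#' random positive outscores a random negative, ties counted half.
#'
#' @inheritParams aupr
#' @return Area in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  check_two_classes(labels, scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_classes <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present to compute a ranking metric",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Threshold at the k-th largest score
#'
#' Returns the value of the k-th most significant relatedness coefficient.
#' Selecting pairs with `score >= mu` can keep more than `k` pairs when ties
#' sit exactly at the threshold.
#'
#' @param scores Numeric vector of relatedness scores.
#' @param k Rank of the score used as threshold, `1 <= k <= length(scores)`.
#' @return The threshold `mu`.
#' @export
top_k_threshold <- function(scores, k) {
  if (k < 1 || k > length(scores)) {
    stop(sprintf("k = %d out of range [1, %d]", k, length(scores)),
         call. = FALSE)
  }
  sort(scores, decreasing = TRUE)[k]
}

#' Confusion counts at a score threshold
#'
#' Pairs with `score >= mu` are called interactions; the rest are called
#' non-interactions. The counts always satisfy `TP + FP + TN + FN = N` and
#' `TP + FN = number of positive labels`.
#'
#' @param labels Binary vector.
#' @param scores Score vector of equal length.
#' @param mu Decision threshold.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(labels, scores, mu) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  called <- scores >= mu
  c(TP = sum(labels == 1 & called),
    FP = sum(labels == 0 & called),
    TN = sum(labels == 0 & !called),
    FN = sum(labels == 1 & !called))
}
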