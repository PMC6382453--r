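check_binary_labels <- function(labels) {
  lev <- sort(unique(labels))
  if (length(lev) != 2L || !all(lev %in% c(0, 1))) {
    rlang::abort("`labels` must be 0/1 with both classes present.")
  }
  invisible(labels)
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive's score outranks a random negative's,
#' ties counted one half; identical to the trapezoidal area under the
#' empirical ROC curve. Computed from midranks in O(n log n).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary 0/1 outcome, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  check_binary_labels(labels)
  if (length(scores) != length(labels) || any(!is.finite(scores))) {
    rlang::abort("`scores` must be finite and aligned with `labels`.")
  }
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' One row per distinct score threshold (descending, bracketed by +Inf and
#' -Inf so the endpoints (sens 0, spec 1) and (sens 1, spec 0) are always
#' present), with the classification rule score >= threshold = positive.
#'
#' @inheritParams auc_mann_whitney
#' @return Tibble of class `ogtt_roc` with `threshold`, `sens`, `spec`.
#' @export
roc_curve <- function(scores, labels) {
  check_binary_labels(labels)
  u <- sort(unique(scores), decreasing = TRUE)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  pos_at <- tabulate(match(scores[labels == 1], u), nbins = length(u))
  neg_at <- tabulate(match(scores[labels == 0], u), nbins = length(u))
  out <- tibble::tibble(
    threshold = c(Inf, u, -Inf),
    sens = c(0, cumsum(pos_at) / m, 1),
    spec = c(1, 1 - cumsum(neg_at) / n, 0)
  )
  class(out) <- unique(c("ogtt_roc", class(out)))
  out
}

#' F-index optimal cutoff
#'
#' The threshold maximizing the harmonic mean of sensitivity and specificity
#' (F-index), the cutoff-selection rule of the benchmark; the harmonic mean
#' is defined as 0 when either component is 0. Ties are broken toward the
#' higher sensitivity.
#'
#' @param roc An [roc_curve()] tibble.
#' @return One-row tibble with `threshold`, `sens`, `spec`, `f_index`.
#' @export
f_index_cutoff <- function(roc) {
  s <- roc$sens
  p <- roc$spec
  f <- ifelse(s + p == 0, 0, 2 * s * p / (s + p))
  best <- which(f == max(f))
  best <- best[which.max(s[best])]
  tibble::tibble(threshold = roc$threshold[best], sens = s[best],
                 spec = p[best], f_index = f[best])
}

#' Confusion-matrix metrics at a threshold
#'
#' Accuracy, sensitivity, specificity, PPV and NPV of the rule
#' score >= threshold = predicted progressor. Predictive values with an
#' empty denominator are `NA`, never 0.
#'
#' @inheritParams auc_mann_whitney
#' @param threshold Finite classification cutoff.
#' @return One-row tibble of the five metrics.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_binary_labels(labels)
  if (!is.finite(threshold)) rlang::abort("`threshold` must be finite.")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sens = tp / (tp + fn),
    spec = tn / (tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn)
  )
}
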