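# Independent oracles used to check the fast implementations.

# Naive O(mn) DeLong structural components by the defining double sum.
naive_delong <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(y))
}

naive_delong_variance <- function(scores, labels) {
  cp <- naive_delong(scores, labels)
  stats::var(cp$v10) / cp$m + stats::var(cp$v01) / cp$n
}

# Brute-force pair-counting AUC.
pair_count_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Two-sided Fisher p by full enumeration of hypergeometric tables at fixed
# margins, summing probabilities <= the observed table's (with a relative
# tolerance for float comparison, as in the standard convention).
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch t statistic and df straight from the textbook formulas.
textbook_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# A small synthetic cohort fixture shared across tests.
toy_cohort <- function(n = 200, seed = 99, missing = TRUE) {
  mr <- if (missing) NULL else stats::setNames(0, marker_order()[1])
  generate_cohort(
    sim_config(n = n, n_progressors = round(n * 146 / 543),
               missing_rate = mr),
    seed = seed
  )
}

# Trapezoidal area under an empirical ROC curve.
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$spec
  sum(diff(fpr) * (utils::head(roc$sens, -1) + utils::tail(roc$sens, -1)) / 2)
}
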