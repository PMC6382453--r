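#' Positive false discovery rate q-values
#'
#' Storey-style q-values: `q_(i) = min_{t >= p_(i)} pi0 * m * t / #{p <= t}`,
#' computed by the usual sorted stepwise minimization and therefore monotone
#' nondecreasing in p. The null proportion `pi0` is estimated with the
#' fixed-lambda estimator `#{p > lambda} / (m (1 - lambda))` at
#' `lambda = 0.5`, capped at 1; with `pi0_method = "fixed_one"` the estimate
#' is pinned to 1, which reproduces Benjamini-Hochberg adjusted p-values
#' exactly (the conservative switch).
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param pi0_method `"storey"` (default) or `"fixed_one"`.
#' @param lambda Tuning point of the fixed-lambda pi0 estimator.
#' @return Numeric q-values in the input order, with the `pi0` used attached
#'   as an attribute.
#' @export
qvalues <- function(pvals, pi0_method = c("storey", "fixed_one"),
                    lambda = 0.5) {
  pi0_method <- rlang::arg_match(pi0_method)
  if (!length(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    rlang::abort("`pvals` must be in [0, 1].")
  }
  m <- length(pvals)
  pi0 <- if (pi0_method == "fixed_one") 1 else {
    min(1, sum(pvals > lambda) / (m * (1 - lambda)))
  }
  if (pi0 <= 0) pi0 <- 1 / m  # every p tiny; keep q-values defined
  o <- order(pvals)
  q_sorted <- pi0 * m * pvals[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Significance call with two-decimal rounding
#'
#' The benchmark's reporting rule: q-values are rounded to two decimals
#' (round-half-even, the IEC 60559 behaviour of [round()]) and only strict
#' `q < 0.05` after rounding is called significant — so q = 0.049 rounds to
#' 0.05 and is NOT significant, unlike the unrounded rule.
#'
#' @param q Numeric q-values in \[0, 1\].
#' @return Logical vector.
#' @export
significance_call <- function(q) {
  if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
    rlang::abort("`q` must be in [0, 1].")
  }
  round(q, 2) < 0.05
}
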