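# Baseline association tests. These are standard procedures, delegated to
# stats::; the wrappers pin down the conventions used throughout the package
# (two-sided p-values; Fisher p by summing hypergeometric outcomes no more
# probable than the observed table).

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param table A 2x2 matrix (or table) of nonnegative integer counts with
#'   both margins positive.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(1, 11, 9, 3), 2))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) rlang::abort("need a 2x2 table.")
  if (any(table < 0) || any(table != round(table))) {
    rlang::abort("counts must be nonnegative integers.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("both margins must be positive.")
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Welch two-sample t test
#'
#' @param x,y Numeric vectors, each with at least two finite values.
#' @return Tibble with `statistic` (t), `df` (Welch-Satterthwaite) and
#'   `p_value` (two-sided).
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    rlang::abort("each group needs >= 2 finite values.")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Pearson correlation with the t-transform test
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both non-constant;
#'   pairs with a missing member are dropped.
#' @return Tibble with `estimate` (r) and `p_value` (two-sided, on n - 2 df).
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) rlang::abort("need >= 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("constant input vector.")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate), p_value = ht$p.value)
}
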