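#' Regularized least-squares binary classifier
#'
#' Ridge-penalized least squares on a +/-1-coded outcome, the learner used
#' throughout the benchmark. The intercept is unpenalized: with centred
#' features the closed-form solution is
#' `w = (Xc' Xc + lambda I)^-1 Xc' (y - ybar)` and
#' `intercept = ybar - xbar' w`. The fitted scores are used only for
#' ranking, so the +/-1 outcome coding is AUC-invariant.
#'
#' @param X Numeric feature matrix, no missing entries, `n >= 2` rows.
#' @param y Binary outcome, either 0/1 or -1/+1; recoded to -1/+1.
#' @param lambda Ridge penalty `>= 0`. At `lambda = 0` the fit is ordinary
#'   least squares and errors on a collinear design.
#' @return An `ogtt_rls` object with `weights`, `intercept`, `lambda`.
#' @export
fit_rls <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) rlang::abort("`X` must be finite.")
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    rlang::abort("`lambda` must be a single nonnegative number.")
  }
  if (nrow(X) < 2L) rlang::abort("need n >= 2.")
  y <- recode_pm1(y)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  ybar <- mean(y)
  G <- crossprod(Xc)
  es <- eigen(G, symmetric = TRUE)
  if (lambda == 0 && min(es$values) < max(es$values, 1) * 1e-10) {
    rlang::abort("singular system at lambda = 0 (collinear features).")
  }
  rhs <- crossprod(es$vectors, crossprod(Xc, y - ybar))
  w <- es$vectors %*% (rhs / (es$values + lambda))
  w <- drop(w)
  names(w) <- colnames(X)
  structure(
    list(weights = w, intercept = ybar - sum(xbar * w), lambda = lambda),
    class = "ogtt_rls"
  )
}

recode_pm1 <- function(y) {
  lev <- sort(unique(y))
  if (length(lev) != 2L) rlang::abort("`y` must have exactly two levels.")
  if (all(lev == c(-1, 1))) return(as.numeric(y))
  if (all(lev == c(0, 1))) return(ifelse(y == 1, 1, -1))
  rlang::abort("`y` must be coded 0/1 or -1/+1.")
}

#' @export
predict.ogtt_rls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$weights) + object$intercept
}

#' @export
print.ogtt_rls <- function(x, ...) {
  cat("Regularized least-squares classifier (lambda =",
      format(x$lambda), ")\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @rdname fit_rls
#' @param x An `ogtt_rls` fit.
#' @param ... Unused.
#' @method tidy ogtt_rls
#' @export
tidy.ogtt_rls <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights))
  )
}

#' @rdname fit_rls
#' @method glance ogtt_rls
#' @export
glance.ogtt_rls <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_features = length(x$weights))
}

# Ridge path solver: one eigendecomposition of the (centred) Gram matrix is
# reused across the whole lambda grid, which is what keeps the repeated
# nested cross-validation affordable over hundreds of candidate models.
# Returns a k x L weight matrix and the (shared) intercept per lambda.
rls_path <- function(Xc, yc, lambdas) {
  G <- crossprod(Xc)
  es <- eigen(G, symmetric = TRUE)
  rhs <- drop(crossprod(es$vectors, crossprod(Xc, yc)))
  W <- es$vectors %*% (rhs / outer(es$values, lambdas, `+`))
  W
}
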