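#' Cross-validation configuration
#'
#' Settings for the repeated nested cross-validation protocol: stratified
#' outer folds estimate out-of-fold prediction scores; within each outer
#' training set, stratified inner folds select the ridge penalty from
#' `lambda_grid` by maximizing the pooled inner out-of-fold AUC; the whole
#' procedure is repeated with re-randomized folds and the per-participant
#' scores averaged over repetitions. Defaults: 100 repetitions (the
#' benchmark's protocol), 10 outer and 10 inner folds (a standard choice for
#' a cohort of ~543 with ~146 events), and a 2^-10..2^10 penalty grid
#' spanning under- to over-regularized fits on standardized features.
#'
#' @param repetitions Number of repetitions (`>= 1`).
#' @param outer_folds,inner_folds Fold counts (`>= 2`).
#' @param lambda_grid Positive ridge penalties.
#' @param seed Master seed; repetition `r` draws its folds under the derived
#'   seed `seed + r`, so repetitions differ but the run is reproducible.
#' @return A `cv_config` list.
#' @export
cv_config <- function(repetitions = 100L, outer_folds = 10L,
                      inner_folds = 10L, lambda_grid = 2^(-10:10),
                      seed = 1L) {
  if (repetitions < 1L) rlang::abort("`repetitions` must be >= 1.")
  if (outer_folds < 2L || inner_folds < 2L) {
    rlang::abort("fold counts must be >= 2.")
  }
  if (!length(lambda_grid) || any(lambda_grid <= 0)) {
    rlang::abort("`lambda_grid` must be positive and non-empty.")
  }
  structure(list(repetitions = as.integer(repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 lambda_grid = sort(lambda_grid),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Balanced fold labels within each outcome class.
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    f[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  f
}

# Column-wise standardization with training-fold parameters only; a
# zero-variance training column is passed through unscaled (sd treated as 1)
# so binary covariates in small folds cannot blow up.
scale_train_apply <- function(X_train, X_apply) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(train = sweep(sweep(X_train, 2L, mu), 2L, sd, `/`),
       apply = sweep(sweep(X_apply, 2L, mu), 2L, sd, `/`))
}

# Inner CV: pooled out-of-fold scores per lambda on the outer training set;
# returns the lambda with the highest inner AUC (ties resolved toward the
# stronger penalty).
select_lambda <- function(X, y, k, lambda_grid) {
  folds <- stratified_folds(y, k)
  scores <- matrix(NA_real_, nrow(X), length(lambda_grid))
  ypm <- recode_pm1(y)
  for (f in seq_len(k)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2L) next
    std <- scale_train_apply(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    yc <- ypm[!te] - mean(ypm[!te])
    W <- rls_path(std$train, yc, lambda_grid)
    scores[te, ] <- std$apply %*% W
  }
  ok <- !is.na(scores[, 1])
  aucs <- apply(scores[ok, , drop = FALSE], 2L,
                auc_mann_whitney, labels = y[ok])
  best <- which(aucs == max(aucs))
  lambda_grid[max(best)]
}

#' Repeated nested cross-validated prediction scores
#'
#' Runs the full protocol of [cv_config()] for one variable set on the
#' complete-case subcohort and returns one averaged out-of-fold score per
#' participant. Standardization parameters are always estimated on training
#' folds only and applied to the held-out folds, so no information leaks
#' from test to training data.
#'
#' @param cohort An `ogtt_cohort`.
#' @param vars Character vector of marker names (the variable set).
#' @param config A [cv_config()].
#' @return Tibble of class `ogtt_scores`: `participant_id`, `outcome`,
#'   `score` (mean over repetitions), with the number of repetitions as the
#'   `"repetitions"` attribute.
#' @export
nested_cv_scores <- function(cohort, vars, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  if (!length(vars)) rlang::abort("empty variable set.")
  cc <- complete_cases(cohort, vars)
  X <- as.matrix(as.data.frame(cc[vars]))
  y <- cc$outcome
  if (min(table(y)) < config$outer_folds) {
    rlang::abort("each class must have at least `outer_folds` members.")
  }
  total <- numeric(nrow(X))
  ypm <- recode_pm1(y)
  for (r in seq_len(config$repetitions)) {
    rep_scores <- withr::with_seed(config$seed + r, {
      out <- numeric(nrow(X))
      folds <- stratified_folds(y, config$outer_folds)
      for (f in seq_len(config$outer_folds)) {
        te <- folds == f
        lam <- select_lambda(X[!te, , drop = FALSE], y[!te],
                             config$inner_folds, config$lambda_grid)
        std <- scale_train_apply(X[!te, , drop = FALSE],
                                 X[te, , drop = FALSE])
        yc <- ypm[!te] - mean(ypm[!te])
        W <- rls_path(std$train, yc, lam)
        out[te] <- drop(std$apply %*% W)
      }
      out
    })
    total <- total + rep_scores
  }
  out <- tibble::tibble(participant_id = cc$participant_id,
                        outcome = y, score = total / config$repetitions)
  attr(out, "repetitions") <- config$repetitions
  class(out) <- unique(c("ogtt_scores", class(out)))
  out
}
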