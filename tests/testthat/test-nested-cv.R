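test_that("cv_config validates its fields", {
  expect_error(cv_config(repetitions = 0), ">= 1")
  expect_error(cv_config(outer_folds = 1), ">= 2")
  expect_error(cv_config(lambda_grid = c(-1, 1)), "positive")
})

test_that("nested CV is deterministic given the seed", {
  co <- toy_cohort(n = 160, seed = 61, missing = FALSE)
  cfg <- cv_config(repetitions = 3, outer_folds = 5, inner_folds = 5,
                   seed = 7)
  s1 <- nested_cv_scores(co, c("PG60", "mannose"), cfg)
  s2 <- nested_cv_scores(co, c("PG60", "mannose"), cfg)
  expect_identical(s1, s2)
  s3 <- nested_cv_scores(co, c("PG60", "mannose"),
                         cv_config(repetitions = 3, outer_folds = 5,
                                   inner_folds = 5, seed = 8))
  expect_false(identical(s1$score, s3$score))
  expect_error(nested_cv_scores(co, character(), cfg), "empty")
})

test_that("adding a pure-noise feature does not inflate cross-validated AUC", {
  # null cohort: no marker carries signal, so any AUC above the Monte-Carlo
  # band would reveal a standardize-before-split leak
  n <- 300
  cfg0 <- sim_config(
    n = n, n_progressors = 100,
    effects = stats::setNames(rep(0, length(marker_order())), marker_order()),
    missing_rate = c(mannose = 0)
  )
  co <- generate_cohort(cfg0, seed = 63)
  cfg <- cv_config(repetitions = 5, outer_folds = 5, inner_folds = 5,
                   seed = 3)
  base_auc <- auc_mann_whitney(
    nested_cv_scores(co, "PG60", cfg)$score, co$outcome)
  plus_noise <- auc_mann_whitney(
    nested_cv_scores(co, c("PG60", "x_12063"), cfg)$score, co$outcome)
  # a standardize-then-split leak inflates AUC systematically; honest CV on
  # pure noise stays within the Monte-Carlo band around chance
  expect_lt(plus_noise - base_auc, 0.12)
  expect_lt(abs(base_auc - 0.5), 0.1)
  expect_lt(abs(plus_noise - 0.5), 0.1)
})

test_that("averaging over repetitions stabilizes the score vector", {
  co <- toy_cohort(n = 160, seed = 64, missing = FALSE)
  one_a <- nested_cv_scores(co, "PG60", cv_config(1, 5, 5, seed = 11))
  one_b <- nested_cv_scores(co, "PG60", cv_config(1, 5, 5, seed = 21))
  many_a <- nested_cv_scores(co, "PG60", cv_config(15, 5, 5, seed = 11))
  many_b <- nested_cv_scores(co, "PG60", cv_config(15, 5, 5, seed = 21))
  expect_lt(stats::sd(many_a$score - many_b$score),
            stats::sd(one_a$score - one_b$score))
})

test_that("a duplicated signal marker leaves the cross-validated AUC unchanged", {
  co <- toy_cohort(n = 250, seed = 65, missing = FALSE)
  co$PG60_copy <- co$PG60
  attr(co, "marker_names") <- c(marker_names(co), "PG60_copy")
  cfg <- cv_config(repetitions = 5, outer_folds = 5, inner_folds = 5,
                   seed = 5)
  a1 <- auc_mann_whitney(nested_cv_scores(co, "PG60", cfg)$score, co$outcome)
  a2 <- auc_mann_whitney(
    nested_cv_scores(co, c("PG60", "PG60_copy"), cfg)$score, co$outcome)
  expect_lt(abs(a1 - a2), 0.03)
})

test_that("class counts below the outer fold count are rejected", {
  co <- toy_cohort(n = 60, seed = 66, missing = FALSE)
  co2 <- co[c(which(co$outcome == 1)[1:4], which(co$outcome == 0)), ]
  attr(co2, "marker_names") <- marker_names(co)
  class(co2) <- class(co)
  expect_error(
    nested_cv_scores(co2, "PG60", cv_config(1, outer_folds = 10)),
    "outer_folds"
  )
})
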