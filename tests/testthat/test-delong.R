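test_that("fast structural components equal the quadratic-time oracle", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    s <- round(stats::rnorm(n), sample(0:2, 1))
    l <- c(0, 0, 1, 1, stats::rbinom(n - 4, 1, 0.4))
    fast <- ogttbench:::delong_components(s, l)
    naive <- naive_delong(s, l)
    expect_equal(fast$auc, naive$auc)
    expect_equal(fast$v10, naive$v10)
    expect_equal(fast$v01, naive$v01)
    expect_equal(delong_variance(s, l), naive_delong_variance(s, l))
  }
})

test_that("all-tie scores have zero structural variance", {
  s <- rep(1, 40)
  l <- rep(c(0, 1), 20)
  # every component is exactly 1/2, so the closed-form variance is 0
  expect_equal(delong_variance(s, l), 0)
  cp <- ogttbench:::delong_components(s, l)
  expect_equal(cp$v10, rep(0.5, 20))
  expect_equal(cp$v01, rep(0.5, 20))
})

test_that("variance scales as 1/n", {
  set.seed(42)
  s <- stats::rnorm(100) + rep(c(0, 1), 50)
  l <- rep(c(0, 1), 50)
  v1 <- delong_variance(s, l)
  v2 <- delong_variance(rep(s, 2), rep(l, 2))
  expect_lt(abs(v2 / v1 - 0.5), 0.03)
})

test_that("analytic and stratified-bootstrap intervals agree at moderate n", {
  set.seed(43)
  n <- 500
  l <- stats::rbinom(n, 1, 0.3)
  s <- stats::rnorm(n) + 0.95 * l # population AUC ~ 0.75
  a <- delong_ci(s, l, method = "analytic")
  b <- delong_ci(s, l, method = "stratified_bootstrap",
                 replicates = 2000, seed = 9)
  expect_lt(abs(a$ci_low - b$ci_low), 0.02)
  expect_lt(abs(a$ci_high - b$ci_high), 0.02)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
})

test_that("interval width halves when the sample size quadruples", {
  set.seed(44)
  l <- rep(c(0, 1), 250)
  s <- stats::rnorm(500) + 0.9 * l
  a1 <- delong_ci(s, l)
  a4 <- delong_ci(rep(s, 4), rep(l, 4))
  expect_lt(abs((a4$ci_high - a4$ci_low) / (a1$ci_high - a1$ci_low) - 0.5),
            0.05)
})

test_that("perfect separation clips the upper bound at 1", {
  s <- c(1:10, 101:110)
  l <- rep(c(0, 1), each = 10)
  ci <- delong_ci(s, l)
  expect_equal(ci$ci_high, 1)
  expect_equal(ci$auc, 1)
})

test_that("the paired test is antisymmetric and degenerate-safe", {
  set.seed(45)
  n <- 200
  l <- stats::rbinom(n, 1, 0.35)
  a <- stats::rnorm(n) + l
  b <- stats::rnorm(n) + 0.5 * l
  ab <- delong_paired_test(a, b, l)
  ba <- delong_paired_test(b, a, l)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$delta_auc, -ba$delta_auc)

  same <- delong_paired_test(a, a, l)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$delta_auc, 0)
  # monotone transform ranks identically: also degenerate
  mono <- delong_paired_test(a, exp(a), l)
  expect_true(mono$degenerate)

  expect_error(delong_paired_test(a, b[-1], l), "aligned")
})

test_that("the paired test agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(46)
  n <- 150
  l <- c(rep(1, 50), rep(0, 100))
  a <- stats::rnorm(n) + 0.8 * l
  b <- 0.6 * a + stats::rnorm(n, sd = 0.8) + 0.3 * l
  ours <- delong_paired_test(a, b, l)
  ref <- pROC::roc.test(
    pROC::roc(l, a, quiet = TRUE), pROC::roc(l, b, quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_equal(sqrt(delong_variance(a, l)),
               sqrt(pROC::var(pROC::roc(l, a, quiet = TRUE))),
               tolerance = 1e-8)
})
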