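test_that("binormal_auc and calibrate_effect are exact inverses", {
  expect_equal(binormal_auc(0), 0.5)
  expect_gt(binormal_auc(10), 0.999)
  expect_equal(binormal_auc(1), stats::pnorm(1 / sqrt(2)))
  expect_equal(binormal_auc(1), 0.7602, tolerance = 1e-4)
  expect_equal(calibrate_effect(0.75), 0.9539, tolerance = 1e-4)
  expect_lt(calibrate_effect(0.5 + 1e-6), 1e-4)
  for (a in c(0.55, 0.65, 0.75, 0.9, 0.99)) {
    expect_equal(binormal_auc(calibrate_effect(a)), a, tolerance = 1e-10)
  }
  expect_error(calibrate_effect(0.5), "0.5")
  expect_error(calibrate_effect(1), "0.5")
  expect_error(binormal_auc(NA_real_), "finite")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n = 100, n_progressors = 100), "n_progressors")
  expect_error(sim_config(missing_rate = c(mannose = 1)), "\\[0, 1\\)")
  bad <- default_corr_targets()
  bad[1, 2] <- 0.9 # asymmetric
  expect_error(sim_config(corr = bad), "symmetric")
})

test_that("generated cohorts have exact size, class balance and seed determinism", {
  cfg <- sim_config(seed = 5L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 543L)
  expect_equal(sum(co$outcome), 146L)
  expect_false(any(co$status == "T2D"))
  expect_true(all(as.matrix(co[pg_markers()]) > 0, na.rm = TRUE))
  co2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  co3 <- generate_cohort(cfg, seed = 6L)
  expect_false(identical(co$PG60, co3$PG60))
  # class balance is exact for any configuration
  co4 <- generate_cohort(sim_config(n = 101, n_progressors = 13), seed = 2)
  expect_equal(sum(co4$outcome), 13L)
})

test_that("null effects give chance-level single-marker discrimination", {
  cfg0 <- sim_config(
    n = 20000, n_progressors = round(20000 * 146 / 543),
    effects = stats::setNames(rep(0, length(marker_order())), marker_order())
  )
  co0 <- generate_cohort(cfg0, seed = 42)
  for (m in marker_order()) {
    ok <- !is.na(co0[[m]])
    expect_lt(abs(auc_mann_whitney(co0[[m]][ok], co0$outcome[ok]) - 0.5),
              0.01)
  }
})

test_that("the generator recovers its correlation targets at large n", {
  n <- 20000
  co <- generate_cohort(
    sim_config(n = n, n_progressors = round(n * 146 / 543)), seed = 7
  )
  emp <- stats::cor(as.data.frame(co[marker_order()]),
                    use = "pairwise.complete.obs")
  targ <- default_corr_targets()
  # continuous markers: every pairwise correlation within the Monte-Carlo
  # band; dichotomized markers (sex, FH) have zero targets and are checked
  # at the same tolerance
  dev <- abs(emp - targ)
  diag(dev) <- 0
  expect_lt(max(dev), 0.03)
  expect_lt(abs(emp["mannose", "PG30"] - 0.32), 0.03)
  expect_lt(abs(emp["mannose", "PG0"] - 0.30), 0.03)
  expect_lt(abs(emp["AHB", "PG60"] - 0.37), 0.03)
  expect_lt(abs(emp["hyp3_bk", "PG60"] - (-0.25)), 0.03)
  expect_lt(abs(emp["x_12063", "PG120"] - 0.35), 0.03)
})

test_that("calibrated effects reproduce their target single-marker AUC", {
  n <- 20000
  co <- generate_cohort(
    sim_config(n = n, n_progressors = round(n * 146 / 543)), seed = 7
  )
  for (m in c("PG60", "PG30", "mannose", "hba1c")) {
    target <- binormal_auc(abs(default_effects()[[m]]))
    ok <- !is.na(co[[m]])
    expect_lt(abs(auc_mann_whitney(co[[m]][ok], co$outcome[ok]) - target),
              0.02)
  }
  # protective marker discriminates in the inverted direction
  ok <- !is.na(co$hyp3_bk)
  expect_lt(auc_mann_whitney(co$hyp3_bk[ok], co$outcome[ok]), 0.45)
})

test_that("baseline strata approximate the emulated cohort's IFG/IGT mix", {
  n <- 20000
  co <- generate_cohort(
    sim_config(n = n, n_progressors = round(n * 146 / 543)), seed = 12
  )
  frac <- table(co$status) / n
  expect_lt(abs(frac[["IFG"]] - 86 / 543), 0.05)
  expect_lt(abs(frac[["IGT"]] - 112 / 543), 0.05)
})

test_that("an indefinite user correlation matrix is repaired with a message", {
  mk <- c("PG0", "PG60", "mannose")
  corr <- diag(3)
  dimnames(corr) <- list(mk, mk)
  corr["PG0", "PG60"] <- corr["PG60", "PG0"] <- 0.9
  corr["PG0", "mannose"] <- corr["mannose", "PG0"] <- 0.9
  corr["PG60", "mannose"] <- corr["mannose", "PG60"] <- -0.9
  cfg <- sim_config(n = 200, n_progressors = 50, corr = corr,
                    effects = c(PG0 = 0.5, PG60 = 0.5, mannose = 0.2),
                    missing_rate = c(PG0 = 0))
  expect_message(generate_cohort(cfg, seed = 1), "repaired")
})
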