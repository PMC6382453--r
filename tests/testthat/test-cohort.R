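test_that("load_cohort round-trips delimited files and flags missing cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,outcome,PG0,PG120,mannose",
               "a,1,5.0,6.0,0.1",
               "b,0,6.2,8.1,-0.4",
               "c,0,5.5,7.0,1.2"), f)
  co <- load_cohort(f)
  expect_s3_class(co, "ogtt_cohort")
  expect_equal(nrow(co), 3L)
  expect_false(anyNA(co[marker_names(co)]))
  expect_equal(marker_names(co), c("PG0", "PG120", "mannose"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,outcome,PG0,PG120,mannose",
               "a,1,5.0,6.0,0.1",
               "b,0,,8.1,-0.4",
               "c,0,5.5,7.0,1.2"), f2)
  co2 <- load_cohort(f2)
  expect_identical(which(is.na(as.matrix(co2[marker_names(co2)]))), 2L)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,outcome,PG0",
               "a,1,5.0", "b,0,6.2", "c,2,5.5"), f3)
  expect_error(load_cohort(f3), "binary")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  co_big <- toy_cohort(n = 50)
  write_cohort(co_big, f4)
  back <- load_cohort(f4)
  expect_equal(as.data.frame(back[marker_names(back)]),
               as.data.frame(co_big[marker_names(co_big)]))
  expect_equal(back$outcome, co_big$outcome)
})

test_that("schema mapping renames file columns to canonical roles", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,progressed,fasting_glucose",
               "a,1,5.0", "b,0,6.2"), f)
  co <- load_cohort(f, schema = c(participant_id = "id",
                                  outcome = "progressed",
                                  PG0 = "fasting_glucose"))
  expect_equal(marker_names(co), "PG0")
  expect_error(load_cohort(f), "outcome")
})

test_that("WHO classification matches the diagnostic windows", {
  expect_equal(as.character(classify_glycemic_status(6.5, 7.0)), "IFG")
  expect_equal(as.character(classify_glycemic_status(6.0, 8.0)), "IGT")
  expect_equal(as.character(classify_glycemic_status(7.2, 6.0)), "T2D")
  expect_equal(as.character(classify_glycemic_status(5.0, 11.2)), "T2D")
  expect_equal(as.character(classify_glycemic_status(5.5, 7.0)), "NORMAL")
  expect_error(classify_glycemic_status(-1, 7), "positive")
  expect_error(classify_glycemic_status(5, Inf), "positive")
})

test_that("classification partitions the glucose plane with disjoint IFG/IGT", {
  grid <- expand.grid(fpg = seq(3, 9, by = 0.1), pg2h = seq(3, 13, by = 0.1))
  st <- classify_glycemic_status(grid$fpg, grid$pg2h)
  expect_false(anyNA(st))
  ifg <- st == "IFG"
  igt <- st == "IGT"
  expect_true(all(grid$pg2h[ifg] < 7.8))
  expect_true(all(grid$pg2h[igt] >= 7.8))
  expect_true(all(grid$fpg[ifg | igt] < 7.0))
})

test_that("standardize centres, scales, is idempotent and rejects constants", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::var(z), 1)
  expect_equal(standardize(z), z)
  x <- c(4, NA, 7, 1)
  zx <- standardize(x)
  expect_true(is.na(zx[2]))
  expect_equal(mean(zx, na.rm = TRUE), 0)
  expect_error(standardize(c(5, 5, 5)), "constant")
})

test_that("impute_min fills missing cells with the observed minimum", {
  expect_equal(impute_min(c(2, NA, 5)), c(2, 2, 5))
  expect_equal(impute_min(c(3, 1, 2)), c(3, 1, 2))
  expect_error(impute_min(c(NA_real_, NA_real_)), "all-missing")
})

test_that("complete_cases drops exactly the rows missing a set member", {
  co <- toy_cohort(n = 120, missing = FALSE)
  expect_equal(nrow(complete_cases(co, c("PG0", "PG60"))), nrow(co))
  co$PG60[5] <- NA
  expect_equal(nrow(complete_cases(co, c("PG0", "PG60"))), nrow(co) - 1L)
  expect_equal(nrow(complete_cases(co, "PG0")), nrow(co))
  co$PG0[co$outcome == 1] <- NA
  expect_error(complete_cases(co, "PG0"), "outcome level")
  expect_error(complete_cases(co, "nonexistent"), "unknown")
})

test_that("metabolite imputation plus complete cases leaves no missing metabolite", {
  co <- toy_cohort(n = 300, seed = 3)
  expect_true(anyNA(co[metabolite_markers()]))
  imp <- impute_metabolites(co)
  cc <- complete_cases(imp, c("PG60", metabolite_markers()))
  expect_false(anyNA(cc[metabolite_markers()]))
  # non-metabolite columns are untouched by imputation
  expect_identical(imp$INS0, co$INS0)
})

test_that("cohort_summary reports Fisher for binary and Welch for continuous markers", {
  co <- toy_cohort(n = 250, seed = 17)
  s <- cohort_summary(co)
  expect_setequal(s$marker, marker_names(co))
  expect_equal(s$test[s$marker == "sex"], "fisher")
  expect_equal(s$test[s$marker == "PG60"], "welch")
  expect_true(all(s$p_value > 0 & s$p_value <= 1, na.rm = TRUE))
  # strong markers should associate with the outcome
  expect_lt(s$p_value[s$marker == "PG60"], 0.01)
})
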