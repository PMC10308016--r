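test_that("BMI matches the cohort's published sex-specific means", {
  expect_equal(compute_bmi(170.8, 68.3), 23.4, tolerance = 0.1 / 23.4)
  expect_equal(compute_bmi(157.8, 54.4), 21.8, tolerance = 0.1 / 21.8)
  expect_identical(compute_bmi(200, 80), 20)
  expect_error(compute_bmi(-170, 70), "positive")
  expect_error(compute_bmi(170, 0), "positive")
})

test_that("complete-case filtering drops whole persons and is idempotent", {
  co <- make_tiny_cohort(5, blank = list(c(2, -1), c(4, 3)))
  fc <- filter_complete_cases(co)
  expect_equal(fc$n_excluded, 2L)
  expect_setequal(unique(fc$records$person_id), c(1L, 3L, 5L))
  again <- filter_complete_cases(fc$records)
  expect_equal(again$n_excluded, 0L)
  expect_identical(again$records, fc$records)

  all_ok <- filter_complete_cases(make_tiny_cohort(4))
  expect_equal(all_ok$n_excluded, 0L)
  expect_equal(nrow(all_ok$records), 4L * 5L)

  empty <- filter_complete_cases(make_tiny_cohort(3)[0, ])
  expect_equal(empty$n_excluded, 0L)
  expect_equal(nrow(empty$records), 0L)
})

test_that("lifestyle answers missing in an interview year drop the person", {
  co <- make_tiny_cohort(3)
  co$sleeps_well[co$person_id == 2 & co$year_index == 3] <- NA
  # a gap at year -1 is harmless: the questionnaire is required in years 0..3
  co$sleeps_well[co$person_id == 3 & co$year_index == -1] <- NA
  fc <- filter_complete_cases(co)
  expect_equal(fc$n_excluded, 1L)
  expect_setequal(unique(fc$records$person_id), c(1L, 3L))
})

test_that("learning/validation split is exact, disjoint and seed-stable", {
  co <- make_tiny_cohort(30)
  sp <- split_learning_validation(co, 20, 5, seed = 11)
  lid <- unique(sp$learning$person_id)
  vid <- unique(sp$validation$person_id)
  expect_length(lid, 20L)
  expect_length(vid, 5L)
  expect_length(intersect(lid, vid), 0L)
  sp2 <- split_learning_validation(co, 20, 5, seed = 11)
  expect_identical(sp, sp2)
  sp0 <- split_learning_validation(co, 0, 5, seed = 1)
  expect_equal(nrow(sp0$learning), 0L)
  expect_error(split_learning_validation(co, 28, 5, seed = 1), "exceeds")
})

test_that("cohort comparison picks the test by variable type", {
  co <- make_tiny_cohort(10)
  cmp <- compare_cohorts(co, co, c("weight_kg", "sex"))
  expect_equal(cmp$statistic[cmp$variable == "weight_kg"], 0)
  expect_identical(cmp$test, c("student-t", "chi-squared"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))

  # hand-checked chi-squared for the 2x2 table [[30,70],[50,50]]:
  # expected counts 40/60 per cell row, X2 = 2*(100/40) + 2*(100/60) = 8.3333
  a <- data.frame(x = rep(c("y", "n"), c(30, 70)))
  b <- data.frame(x = rep(c("y", "n"), c(50, 50)))
  cc <- compare_cohorts(a, b, "x", year_index = NULL)
  expect_equal(cc$statistic, 25 / 3, tolerance = 1e-10)

  set.seed(1)
  a2 <- data.frame(v = rnorm(100, 0)); b2 <- data.frame(v = rnorm(100, 5))
  c2 <- compare_cohorts(a2, b2, "v", year_index = NULL)
  expect_lt(c2$p_value, 1e-6)
})

test_that("zero-variance continuous variables are flagged, not fatal", {
  a <- data.frame(v = rep(1, 10)); b <- data.frame(v = rep(2, 10))
  cc <- compare_cohorts(a, b, "v", year_index = NULL)
  expect_true(is.na(cc$statistic))
  expect_identical(cc$note, "zero variance")
})

test_that("comparison p-values are uniform under the null", {
  set.seed(42)
  ps <- replicate(1000, {
    a <- data.frame(v = rnorm(30)); b <- data.frame(v = rnorm(30))
    compare_cohorts(a, b, "v", year_index = NULL)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort CSV round-trips with empty cells as missing", {
  co <- make_tiny_cohort(4, blank = list(c(2, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
})
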