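test_that("the packaged model carries the published structure", {
  m <- published
  expect_s3_class(m, "pwl_model")
  expect_length(m$leaves, 5L)
  expect_identical(m$tree$feature, "bmi_baseline")
  expect_equal(m$tree$threshold, 29.93)
  expect_equal(m$leaves[[1]]$bias, 2.12)
  expect_equal(unname(m$leaves[[1]]$terms["weight_baseline"]), 1.00)
  expect_equal(unname(m$leaves[[1]]$terms["weight_diff"]), -0.14)
  # column 3 keeps its literal zero height coefficient as a selected term,
  # distinct from the unselected entries
  expect_true("height_baseline" %in% names(m$leaves[[3]]$terms))
  expect_equal(unname(m$leaves[[3]]$terms["height_baseline"]), 0)
  expect_false("sex_male" %in% names(m$leaves[[1]]$terms))
})

test_that("coefficient drift in the fixture is rejected by the checksum", {
  path <- withr::local_tempfile(fileext = ".json")
  txt <- readLines(system.file("extdata", "published_model.json",
                               package = "weightcast"))
  writeLines(sub('"weight_baseline": 1,', '"weight_baseline": 1.01,', txt), path)
  expect_error(read_model_json(path), "checksum")
})

test_that("leaf routing follows the published thresholds and boundaries", {
  m <- published
  expect_identical(assign_leaf(31.0, 50, "male", m), 1L)
  expect_identical(assign_leaf(31.0, 50, "female", m), 2L)
  # the BMI boundary belongs to the high side
  expect_identical(assign_leaf(29.93, 50, "female", m), 2L)
  expect_identical(assign_leaf(29.92, 50, "female", m), 4L)
  # age 24 is grouped with the young leaf, 25 with the older one
  expect_identical(assign_leaf(25.0, 24, "male", m), 3L)
  expect_identical(assign_leaf(25.0, 25, "male", m), 4L)
  expect_identical(assign_leaf(23.44, 30, "male", m), 4L)
  expect_identical(assign_leaf(23.43, 30, "male", m), 5L)
})

test_that("every BMI/age/sex combination reaches exactly one leaf", {
  set.seed(99)
  n <- 10000
  ids <- assign_leaf(runif(n, 12, 50), sample(19:91, n, TRUE),
                     rbinom(n, 1, 0.5), published)
  expect_true(all(ids %in% 1:5))
  expect_length(ids, n)
  # all five regions are reachable
  expect_setequal(unique(ids), 1:5)
})

test_that("one-year prediction is the published dot product", {
  vocab <- feature_vocabulary()$feature
  fv <- stats::setNames(numeric(length(vocab)), vocab)
  fv[c("weight_baseline", "height_baseline", "age_baseline")] <- c(90, 170, 40)
  expect_equal(predict_one_year(fv, published$leaves[[1]]), 93.02)
  fv5 <- stats::setNames(numeric(length(vocab)), vocab)
  fv5[c("weight_baseline", "height_baseline")] <- c(60, 160)
  expect_equal(predict_one_year(fv5, published$leaves[[5]]), 63.38)
  fv0 <- stats::setNames(numeric(length(vocab)), vocab)
  for (lf in published$leaves) expect_equal(predict_one_year(fv0, lf), lf$bias)
})

test_that("prediction is linear in the continuous block", {
  vocab <- feature_vocabulary()$feature
  lf <- published$leaves[[2]]
  f0 <- stats::setNames(numeric(length(vocab)), vocab)
  fx <- f0
  fx[c("weight_baseline", "weight_diff", "height_baseline", "drinking_pred")] <-
    c(70, 2, 160, 4)
  for (alpha in c(0.5, 2, -1)) {
    fa <- f0
    fa[names(fx)] <- alpha * fx
    expect_equal(predict_one_year(fa, lf) - predict_one_year(f0, lf),
                 alpha * (predict_one_year(fx, lf) - predict_one_year(f0, lf)))
  }
})

test_that("model JSON round-trip is the identity on all coefficients", {
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(published, path)
  back <- read_model_json(path)
  expect_equal(back$tree, published$tree)
  for (j in 1:5) {
    expect_identical(back$leaves[[j]]$bias, published$leaves[[j]]$bias)
    expect_identical(back$leaves[[j]]$terms, published$leaves[[j]]$terms)
  }
})

test_that("trajectories chain: horizon 1 equals the one-year prediction", {
  h <- make_history(90, 90, 170, 40, "male")
  pred <- silent_pred_profile()
  tr1 <- predict_trajectory(h, pred, published, horizon = 1,
                            advance_age = FALSE)
  expect_length(tr1$predicted, 1L)
  expect_equal(tr1$predicted, 93.02)
  tr3 <- predict_trajectory(h, pred, published, horizon = 3)
  expect_length(tr3$predicted, 3L)
  expect_length(tr3$measured, 2L)
  expect_true(all(is.finite(tr3$predicted)))
  expect_equal(tr3$predicted[1], tr1$predicted)
  expect_error(predict_trajectory(h, pred, published, horizon = 0), "horizon")
})

test_that("an identity-like one-leaf model chains to w0 + k*b", {
  m <- identity_model(bias = 0.7, weight_coef = 1)
  h <- make_history(80, 80, 175, 50, "male")
  tr <- predict_trajectory(h, silent_pred_profile(), m, horizon = 3,
                           reassign_leaf = FALSE)
  expect_equal(tr$predicted, 80 + 0.7 * (1:3))
})

test_that("healthier scenarios do not raise predicted weight", {
  h <- make_history(90, 90, 170, 40, "male")  # formula-1 subject
  skip_bf <- silent_pred_profile(); skip_bf$skips_breakfast_3x <- "yes"
  eat_bf <- silent_pred_profile(); eat_bf$skips_breakfast_3x <- "no"
  for (intent in 1:3) {
    skip_bf$intention_level <- eat_bf$intention_level <- intent
    if (intent != 2) {
      # keep the exercise item silent at every intention level
      skip_bf$exercise_2x30min <- eat_bf$exercise_2x30min <- "yes"
    }
    tt <- scenario_compare(h, eat_bf, skip_bf, published)
    expect_true(all(tt[[1]]$predicted <= tt[[2]]$predicted + 1e-12))
  }
  fast <- silent_pred_profile(); fast$fast_walker <- "yes"
  fast$intention_level <- 1L; fast$exercise_2x30min <- "yes"
  slow <- fast; slow$fast_walker <- "no"
  tw <- scenario_compare(h, fast, slow, published)
  expect_true(all(tw[[1]]$predicted <= tw[[2]]$predicted + 1e-12))
})

test_that("identical scenarios warn and coincide", {
  h <- make_history(90, 90, 170, 40, "male")
  s <- silent_pred_profile()
  expect_warning(tt <- scenario_compare(h, s, s, published), "identical")
  expect_equal(tt[[1]]$predicted, tt[[2]]$predicted)
})
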