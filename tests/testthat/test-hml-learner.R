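test_that("leaf regression recovers a known sparse linear rule", {
  set.seed(11)
  n <- 5000
  X <- cbind(weight_baseline = runif(n, 50, 100),
             weight_diff = rnorm(n, 0, 2),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- 2.12 + 1.0 * X[, "weight_baseline"] + rnorm(n, 0, 0.01)
  lf <- fit_leaf_regression(X, y, fit_config())
  expect_equal(unname(lf$terms["weight_baseline"]), 1.00, tolerance = 0.02)
  expect_equal(lf$bias, 2.12, tolerance = 0.1 / 2.12)
  expect_false("noise1" %in% names(lf$terms) && abs(lf$terms["noise1"]) > 0.01)
})

test_that("pure-noise decoys are selected at most at the criterion's rate", {
  set.seed(12)
  rates <- replicate(100, {
    n <- 200
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("d", 1:5)))
    y <- rnorm(n)
    lf <- fit_leaf_regression(X, y, fit_config(min_leaf_n = 50))
    length(lf$terms) / 5
  })
  # BIC admits a null feature with prob ~ P(chisq_1 > log n) ~= 0.02
  expect_lte(mean(rates), 0.05)
})

test_that("undersized leaves are a precondition error", {
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_leaf_regression(X, rnorm(50), fit_config(min_leaf_n = 200)),
               "min_leaf_n")
})

test_that("the greedy split step equals the brute-force oracle", {
  cfg <- fit_config(min_leaf_n = 30, threshold_grid = 8)
  mismatches <- 0L
  for (s in 1:50) {
    nd <- random_split_instance(n = sample(80:300, 1), shift = runif(1, 0, 2),
                                seed = 1000 + s)
    fast <- weightcast:::find_best_split(nd, cfg, refine = FALSE)
    slow <- brute_force_best_split(nd, cfg)
    if (is.na(slow$feature)) {
      ok <- is.null(fast$feature) || !is.finite(fast$gain) || fast$gain <= 0
    } else {
      ok <- identical(fast$feature, slow$feature) &&
        isTRUE(all.equal(fast$threshold, slow$threshold)) &&
        isTRUE(all.equal(fast$gain, slow$gain, tolerance = 1e-6))
    }
    if (!ok) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("score_split is deterministic and flags infeasible children", {
  nd <- random_split_instance(300, shift = 1.5, seed = 77)
  cfg <- fit_config(min_leaf_n = 50)
  s1 <- score_split(nd, "bmi_baseline", 26, cfg)
  s2 <- score_split(nd, "bmi_baseline", 26, cfg)
  expect_identical(s1, s2)
  expect_true(s1$feasible)
  tiny <- score_split(nd, "bmi_baseline", max(nd$bmi_baseline) - 1e-9, cfg)
  expect_false(tiny$feasible)
  expect_identical(tiny$gain, -Inf)
})

test_that("single-regime data gives non-positive expected split gain", {
  cfg <- fit_config(min_leaf_n = 40, threshold_grid = 16)
  set.seed(13)
  gains <- numeric(50)
  n_split <- 0L
  for (i in 1:50) {
    nd <- random_split_instance(400, shift = 0, seed = sample.int(1e6, 1))
    gains[i] <- score_split(nd, "bmi_baseline",
                            stats::median(nd$bmi_baseline), cfg)$gain
    fit <- fit_partition(nd, cfg)
    if (length(fit$model$leaves) > 1) n_split <- n_split + 1L
  }
  # any fixed candidate loses in expectation under the null ...
  expect_lt(mean(gains), 0)
  # ... and even maximising over ~33 candidates rarely turns a profit
  expect_lte(n_split, 10L)
})

test_that("a strong two-regime boundary is located within a grid step", {
  set.seed(14)
  nd <- random_split_instance(2000, shift = 5, seed = 500)
  cfg <- fit_config(min_leaf_n = 100, threshold_grid = 64, max_depth = 1)
  fit <- fit_partition(nd, cfg)
  expect_length(fit$model$leaves, 2L)
  expect_identical(fit$trace$feature, "bmi_baseline")
  grid_step <- diff(range(nd$bmi_baseline)) / 64
  expect_lt(abs(fit$trace$threshold - 26), grid_step)
})

test_that("accepted splits always improve the penalised criterion", {
  nd <- random_split_instance(1500, shift = 3, seed = 900)
  fit <- fit_partition(nd, fit_config(min_leaf_n = 60))
  if (!is.null(fit$trace)) expect_true(all(fit$trace$gain > 0))
  # every training row lands in exactly one leaf
  ids <- assign_leaf(nd$bmi_baseline, nd$age_baseline, nd$sex_male, fit$model)
  expect_true(all(ids %in% vapply(fit$model$leaves, `[[`, 1L, "id")))
  expect_equal(sum(fit$leaf_n), nrow(nd))
})

test_that("a constant target yields one all-zero leaf", {
  nd <- random_split_instance(600, shift = 0, seed = 321)
  nd$next_weight <- 5
  fit <- fit_partition(nd, fit_config(min_leaf_n = 50))
  expect_length(fit$model$leaves, 1L)
  expect_length(fit$model$leaves[[1]]$terms, 0L)
  expect_equal(fit$model$leaves[[1]]$bias, 5)
})

test_that("fitting is deterministic given data and config", {
  nd <- random_split_instance(800, shift = 2, seed = 55)
  cfg <- fit_config(min_leaf_n = 60)
  f1 <- fit_partition(nd, cfg)
  f2 <- fit_partition(nd, cfg)
  expect_identical(f1$model$tree, f2$model$tree)
  expect_identical(f1$model$leaves, f2$model$leaves)
  expect_error(fit_partition(nd[0, ], cfg), "empty")
})
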