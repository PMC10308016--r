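test_that("rmse matches its closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(rep(0, 7), rep(2.5, 7)), 2.5)
  expect_equal(rmse(data.frame(y_true = c(0, 0), y_pred = c(3, 4))),
               sqrt(12.5))
  # permutation invariance and non-negativity
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50); p <- sample(50)
  expect_equal(rmse(a, b), rmse(a[p], b[p]))
  expect_gte(rmse(a, b), 0)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("the multiple-regression baseline interpolates single-leaf truth", {
  truth <- identity_model(bias = 0.4, weight_coef = 1)
  cfg <- test_gen_config(600, seed = 41, noise_sd_kg = 0,
                         ground_truth_model = truth)
  co <- generate_cohort(cfg)
  tr <- encode_transitions(co, include_labs = FALSE)
  base <- suppressWarnings(fit_multiple_regression(tr))
  expect_length(base$leaves, 1L)
  ev <- evaluate_model(base, co, lifestyle = "observed")
  expect_lt(ev$rmse, 1e-6)
})

test_that("baseline RMSE approaches the noise floor on one-regime data", {
  truth <- identity_model(bias = 0.4, weight_coef = 1)
  cfg <- test_gen_config(4000, seed = 42, noise_sd_kg = 1,
                         ground_truth_model = truth)
  co <- generate_cohort(cfg)
  sp <- split_learning_validation(co, 3000, 1000, seed = 1)
  base <- suppressWarnings(fit_multiple_regression(
    encode_transitions(sp$learning, include_labs = FALSE)))
  ev <- evaluate_model(base, sp$validation, lifestyle = "observed")
  # the one-year-ahead error has no chaining accumulation
  expect_equal(unname(ev$rmse_by_horizon["year1"]), 1, tolerance = 0.05)
})

test_that("the true piecewise model beats the global baseline on 5-leaf data", {
  for (s in c(61, 62, 63)) {
    cfg <- test_gen_config(2500, seed = s, noise_sd_kg = 1)
    co <- generate_cohort(cfg)
    sp <- split_learning_validation(co, 1800, 700, seed = s)
    base <- suppressWarnings(fit_multiple_regression(
      encode_transitions(sp$learning, include_labs = FALSE)))
    ev_pw <- evaluate_model(published, sp$validation)
    ev_mr <- evaluate_model(base, sp$validation)
    expect_lte(ev_pw$rmse, ev_mr$rmse)
  }
})

test_that("chained evaluation of the generating model hits the noise floor", {
  cfg <- test_gen_config(5000, seed = 43, noise_sd_kg = 1)
  co <- generate_cohort(cfg)
  ev <- evaluate_model(published, co, lifestyle = "observed")
  expect_equal(unname(ev$rmse_by_horizon["year1"]), 1, tolerance = 0.05)
  # later horizons compound the fed-forward innovation
  expect_gt(unname(ev$rmse_by_horizon["year3"]),
            unname(ev$rmse_by_horizon["year1"]))
})

test_that("model comparison detects separated error scales and not the null", {
  set.seed(3)
  a <- rnorm(5000, sd = 1)^2
  b <- rnorm(5000, sd = 2)^2
  cm <- compare_models(a, b)
  expect_lt(cm$p_value, 1e-6)
  same <- compare_models(a, a, paired = TRUE)
  expect_true(is.na(same$statistic) || abs(same$statistic) < 1e-8)
  ident <- compare_models(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(ident$statistic))
})

test_that("recovery of the model from itself is exact and label-invariant", {
  rec <- recovery_report(published, published)
  expect_true(rec$leaf_count_match)
  expect_equal(max(rec$gates$abs_error), 0)
  expect_equal(max(rec$coef_errors$max_abs_coef_error), 0)
  expect_equal(unname(rec$weight_coefs), rep(1, 5))
  expect_equal(rec$weight_diff_coef_leaf1, -0.14)

  # permute leaf ids (and the tree's references): region matching is id-blind
  perm <- c(3L, 5L, 4L, 1L, 2L)
  relabel <- function(node) {
    if (node$kind == "leaf") return(weightcast:::new_leaf_node(perm[node$leaf]))
    node$left <- relabel(node$left); node$right <- relabel(node$right)
    node
  }
  leaves2 <- lapply(published$leaves, function(l) {
    weightcast:::new_leaf_formula(perm[l$id], l$bias, l$terms)
  })
  shuffled <- pwl_model(relabel(published$tree), leaves2)
  rec2 <- recovery_report(published, shuffled)
  expect_equal(max(rec2$coef_errors$max_abs_coef_error), 0)
  expect_equal(rec2$weight_diff_coef_leaf1, -0.14)
})

test_that("recovery against a disjoint vocabulary errors", {
  odd <- pwl_model(weightcast:::new_leaf_node(1L),
                   list(weightcast:::new_leaf_formula(1L, 0, c(zzz = 1))))
  expect_error(recovery_report(published, odd), "vocabulary")
})
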