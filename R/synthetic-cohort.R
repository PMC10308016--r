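# Synthetic longitudinal checkup cohorts. Baseline anthropometry follows the
# published cohort characteristics (sex-specific normals, age 48 +/- 12
# truncated to 19-91); weights for years 1..3 are simulated forward from a
# ground-truth piecewise-linear model plus Gaussian noise; lifestyle answers
# persist year to year with a small flip probability; missingness is injected
# MCAR at the person level.

default_lifestyle_marginals <- function() {
  list(
    wants_health_instruction = 0.30,
    heavy_smoker = 0.25,
    fast_walker = 0.45,
    daily_activity_1h = 0.35,
    exercise_2x30min = 0.25,
    skips_breakfast_3x = 0.20,
    late_supper_3x = 0.35,
    snacks_between_meals = 0.35,
    sleeps_well = 0.70,
    eating_speed = c(quicker = 0.30, normal = 0.55, slower = 0.15),
    drinking_score = c(0.35, 0.15, 0.12, 0.10, 0.08, 0.06, 0.05, 0.04,
                       0.03, 0.01, 0.01),
    intention_level = c(0.35, 0.40, 0.25)
  )
}

# Sex-specific marginals of the baseline anthropometry and labs
default_sex_params <- function() {
  list(
    male = list(height = c(170.8, 6.2), weight = c(68.3, 11.1),
                labs = list(waist_cm = c(83.5, 9.3), SBP = c(124, 16),
                            DBP = c(78, 11), HbA1c = c(5.6, 0.5),
                            TG = c(122, 79), HDL_C = c(59, 15),
                            LDL_C = c(123, 30), FBG = c(99, 14),
                            AST = c(25, 10), ALT = c(26, 16),
                            GGTP = c(49, 43))),
    female = list(height = c(157.8, 5.7), weight = c(54.4, 9.6),
                  labs = list(waist_cm = c(78.4, 9.6), SBP = c(117, 16),
                              DBP = c(72, 11), HbA1c = c(5.6, 0.4),
                              TG = c(87, 51), HDL_C = c(70, 16),
                              LDL_C = c(119, 30), FBG = c(94, 11),
                              AST = c(21, 7), ALT = c(16, 9),
                              GGTP = c(25, 20)))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the published cohort: 66% male, sex-specific
#' height/weight normals, age normal(48, 12) truncated to 19-91, per-person
#' missingness probability 12021/67021, weight noise 1.9 kg (calibrated to the
#' scale of the reported validation RMSE), and the packaged published model as
#' the ground truth driving the weight dynamics.
#'
#' @param n_persons Number of persons to generate.
#' @param seed Integer seed; the cohort is fully reproducible given it.
#' @param male_fraction Probability of male sex.
#' @param noise_sd_kg SD (kg) of the Gaussian innovation added to each
#'   one-year model prediction.
#' @param missingness_prob Per-person probability of carrying a missing
#'   required field (injected as a blanked weight in one random year).
#' @param lifestyle_flip_prob Year-to-year probability that an answer changes.
#' @param ground_truth_model `pwl_model` generating the weight dynamics
#'   (default: the published model).
#' @param include_labs Also draw the lab panel (independent sex-specific
#'   normals; decoy predictors for the learner).
#' @param advance_age Age increases by 1 per year during simulation
#'   (`FALSE` freezes age at its baseline value).
#' @param reassign_leaf Re-evaluate the gating tree each simulated year with
#'   the updated BMI.
#' @param lifestyle_marginals,sex_params Advanced overrides of the answer and
#'   anthropometry marginals (see package vignette).
#' @param age_mean,age_sd,age_range Age distribution parameters.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_persons, seed = 1L,
                             male_fraction = 0.66,
                             noise_sd_kg = 1.9,
                             missingness_prob = 12021 / 67021,
                             lifestyle_flip_prob = 0.1,
                             ground_truth_model = NULL,
                             include_labs = TRUE,
                             advance_age = TRUE,
                             reassign_leaf = TRUE,
                             lifestyle_marginals = default_lifestyle_marginals(),
                             sex_params = default_sex_params(),
                             age_mean = 48, age_sd = 12, age_range = c(19, 91)) {
  stopifnot(is.numeric(n_persons), n_persons >= 1)
  assert_prob(male_fraction, "male_fraction")
  assert_prob(missingness_prob, "missingness_prob")
  assert_prob(lifestyle_flip_prob, "lifestyle_flip_prob")
  if (!is.numeric(noise_sd_kg) || noise_sd_kg < 0) {
    stop_domain("noise_sd_kg must be >= 0")
  }
  for (nm in setdiff(names(lifestyle_marginals), character(0))) {
    assert_prob(lifestyle_marginals[[nm]], paste0("lifestyle_marginals$", nm))
  }
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    male_fraction = male_fraction, noise_sd_kg = noise_sd_kg,
    missingness_prob = missingness_prob,
    lifestyle_flip_prob = lifestyle_flip_prob,
    ground_truth_model = ground_truth_model,
    include_labs = include_labs, advance_age = advance_age,
    reassign_leaf = reassign_leaf,
    lifestyle_marginals = lifestyle_marginals, sex_params = sex_params,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range
  ), class = "generator_config")
}

r_truncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_lifestyle <- function(n, marg) {
  out <- data.frame(row.names = seq_len(n))
  for (item in lifestyle_binary_items()) {
    out[[item]] <- ifelse(stats::runif(n) < marg[[item]], "yes", "no")
  }
  es <- marg$eating_speed
  out$eating_speed <- sample(names(es), n, replace = TRUE, prob = es)
  ds <- marg$drinking_score
  out$drinking_score <- sample(seq_along(ds) - 1L, n, replace = TRUE, prob = ds)
  il <- marg$intention_level
  out$intention_level <- sample(1:3, n, replace = TRUE, prob = il)
  out[, lifestyle_columns(), drop = FALSE]
}

evolve_lifestyle <- function(prev, marg, flip_prob) {
  n <- nrow(prev)
  out <- prev
  for (item in lifestyle_binary_items()) {
    flip <- stats::runif(n) < flip_prob
    out[[item]] <- ifelse(flip,
                          ifelse(prev[[item]] == "yes", "no", "yes"),
                          prev[[item]])
  }
  redraw <- function(col, draw) ifelse(stats::runif(n) < flip_prob, draw, col)
  es <- marg$eating_speed
  out$eating_speed <- redraw(prev$eating_speed,
                             sample(names(es), n, replace = TRUE, prob = es))
  ds <- marg$drinking_score
  out$drinking_score <- as.integer(redraw(
    prev$drinking_score,
    sample(seq_along(ds) - 1L, n, replace = TRUE, prob = ds)))
  il <- marg$intention_level
  out$intention_level <- as.integer(redraw(
    prev$intention_level, sample(1:3, n, replace = TRUE, prob = il)))
  out
}

#' Generate a synthetic longitudinal checkup cohort
#'
#' Draws baseline anthropometry and lifestyle from the configured marginals,
#' simulates weights for years 1..3 by chaining the ground-truth model with
#' Gaussian noise (the year-0 weight is the year -1 weight plus one noise
#' innovation, giving the weight-difference covariate its working scale), and
#' finally injects person-level MCAR missingness.
#'
#' @param config A [generator_config()].
#' @return Cohort tibble: one row per person-year (years -1..3), in the
#'   package's cohort CSV dialect.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  model <- config$ground_truth_model %||% load_published_model()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_persons
  marg <- config$lifestyle_marginals

  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  sp <- config$sex_params
  height <- ifelse(sex == "male",
                   stats::rnorm(n, sp$male$height[1], sp$male$height[2]),
                   stats::rnorm(n, sp$female$height[1], sp$female$height[2]))
  w_m1 <- ifelse(sex == "male",
                 stats::rnorm(n, sp$male$weight[1], sp$male$weight[2]),
                 stats::rnorm(n, sp$female$weight[1], sp$female$weight[2]))
  w_m1 <- pmax(w_m1, 30)
  height <- pmax(height, 120)
  age0 <- round(r_truncnorm(n, config$age_mean, config$age_sd,
                            config$age_range[1] - 0.5, config$age_range[2] + 0.5))
  age0 <- pmin(pmax(age0, config$age_range[1]), config$age_range[2])
  w_0 <- w_m1 + stats::rnorm(n, 0, config$noise_sd_kg)

  ls <- vector("list", 5L)            # lifestyle frames for years -1..3
  ls[[1]] <- draw_lifestyle(n, marg)
  for (k in 2:5) ls[[k]] <- evolve_lifestyle(ls[[k - 1]], marg,
                                             config$lifestyle_flip_prob)

  noise <- matrix(stats::rnorm(n * 3L, 0, config$noise_sd_kg), n, 3L)
  state <- data.frame(weight_prev = w_m1, weight_base = w_0,
                      height_cm = height, age = age0,
                      sex_male = as.numeric(sex == "male"))
  W <- chain_forecast(model, state,
                      base_profiles = ls[2:4], pred_profiles = ls[3:5],
                      horizon = 3L, reassign_leaf = config$reassign_leaf,
                      advance_age = config$advance_age, noise = noise)

  weights <- cbind(w_m1, w_0, W)
  miss_person <- stats::runif(n) < config$missingness_prob
  miss_year <- sample.int(5L, n, replace = TRUE)
  weights[cbind(which(miss_person), miss_year[miss_person])] <- NA_real_

  labs <- NULL
  if (config$include_labs) {
    labs <- data.frame(row.names = seq_len(n))
    for (lc in lab_columns()) {
      pm <- sp$male$labs[[lc]]; pf <- sp$female$labs[[lc]]
      labs[[lc]] <- round(ifelse(sex == "male",
                                 stats::rnorm(n, pm[1], pm[2]),
                                 stats::rnorm(n, pf[1], pf[2])), 1)
    }
  }

  rows <- lapply(1:5, function(k) {
    yr <- k - 2L
    d <- tibble::tibble(
      person_id = seq_len(n),
      year_index = yr,
      sex = sex,
      age = if (config$advance_age) age0 + max(yr, 0L) else age0,
      height_cm = height,
      weight_kg = weights[, k]
    )
    if (!is.null(labs)) d <- cbind(d, labs)
    cbind(d, ls[[k]])
  })
  cohort <- tibble::as_tibble(do.call(rbind, rows))
  cohort <- cohort[order(cohort$person_id, cohort$year_index), ]
  rownames(cohort) <- NULL
  cohort
}

#' Simulate one person's noisy weight trajectory
#'
#' Forward-simulates years 1..3 by iterating the one-year model, feeding each
#' realised (noisy) weight forward and updating the weight-difference
#' covariate. With `noise_sd_kg = 0` this reproduces the model's chained
#' predictions exactly.
#'
#' @param history Data frame with the person's year -1 and 0 records (as for
#'   [predict_trajectory()]).
#' @param model A `pwl_model`.
#' @param noise_sd_kg Innovation SD in kg.
#' @param lifestyle_pred One-row lifestyle frame held fixed over the horizon
#'   (default: the year-0 profile).
#' @param horizon Years to simulate.
#' @inheritParams predict_trajectory
#' @return Numeric vector of realised weights for years 1..horizon.
#' @export
simulate_weight_trajectory <- function(history, model, noise_sd_kg,
                                       lifestyle_pred = NULL, horizon = 3,
                                       reassign_leaf = TRUE,
                                       advance_age = TRUE) {
  ps <- person_state(history)
  scen <- (lifestyle_pred %||% ps$baseline_profile)[, lifestyle_columns(),
                                                    drop = FALSE]
  base_profiles <- c(list(ps$baseline_profile),
                     rep(list(scen), max(0L, horizon - 1L)))
  noise <- matrix(stats::rnorm(horizon, 0, noise_sd_kg), 1L, horizon)
  W <- chain_forecast(model, ps$state, base_profiles,
                      rep(list(scen), horizon), horizon,
                      reassign_leaf = reassign_leaf, advance_age = advance_age,
                      noise = noise)
  drop(W[1L, ])
}
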