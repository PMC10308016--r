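# Shared fixtures, all built in code at test time.

published <- load_published_model()

# A lifestyle profile whose baseline-interview indicators all stay silent
# (answers at the complement of every baseline feature level).
silent_base_profile <- function(intent = 2L) {
  data.frame(
    wants_health_instruction = "yes", heavy_smoker = "yes",
    drinking_score = 0, fast_walker = "yes", daily_activity_1h = "yes",
    exercise_2x30min = "yes", skips_breakfast_3x = "no",
    eating_speed = "slower", late_supper_3x = "no",
    snacks_between_meals = "no", sleeps_well = "yes",
    intention_level = intent
  )
}

# A predictive-year profile whose indicators all stay silent. Intention must
# be 2: with answer "no" the exercise item then matches no feature row.
silent_pred_profile <- function() {
  data.frame(
    wants_health_instruction = "no", heavy_smoker = "yes",
    drinking_score = 0, fast_walker = "no", daily_activity_1h = "no",
    exercise_2x30min = "no", skips_breakfast_3x = "yes",
    eating_speed = "quicker", late_supper_3x = "yes",
    snacks_between_meals = "yes", sleeps_well = "no",
    intention_level = 2L
  )
}

# Two-row (years -1, 0) measured history with a silent baseline profile.
make_history <- function(weight_m1, weight_0, height_cm, age, sex,
                         profile = silent_base_profile()) {
  h <- rbind(
    cbind(data.frame(person_id = 1L, year_index = -1L, sex = sex, age = age,
                     height_cm = height_cm, weight_kg = weight_m1), profile),
    cbind(data.frame(person_id = 1L, year_index = 0L, sex = sex, age = age,
                     height_cm = height_cm, weight_kg = weight_0), profile)
  )
  h
}

# Tiny hand-built cohort: n persons x years -1..3, constant weights, useful
# for filtering/splitting tests. Weights can be blanked per (person, year).
make_tiny_cohort <- function(n = 5L, blank = NULL) {
  prof <- silent_base_profile()
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(-1:3, function(y) {
      cbind(data.frame(person_id = i, year_index = y,
                       sex = if (i %% 2) "male" else "female",
                       age = 40 + i, height_cm = 170, weight_kg = 70 + i),
            prof)
    }))
  }))
  if (!is.null(blank)) {
    for (b in blank) {
      rows$weight_kg[rows$person_id == b[1] & rows$year_index == b[2]] <- NA
    }
  }
  tibble::as_tibble(rows)
}

# Single-leaf model: next weight = bias + coef * current weight.
identity_model <- function(bias = 0, weight_coef = 1) {
  pwl_model(weightcast:::new_leaf_node(1L),
            list(weightcast:::new_leaf_formula(
              1L, bias, c(weight_baseline = weight_coef))))
}

# Random small transition-like table for split-search oracle tests: two
# plain features, gates, and a response with an optional regime shift.
random_split_instance <- function(n, shift = 0, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(
    bmi_baseline = stats::runif(n, 18, 35),
    age_baseline = sample(20:70, n, replace = TRUE),
    sex_male = stats::rbinom(n, 1, 0.5),
    f1 = stats::rnorm(n),
    f2 = stats::rnorm(n)
  )
  regime <- as.numeric(d$bmi_baseline >= 26)
  d$next_weight <- 1 + 0.5 * d$f1 + shift * regime * (1 + d$f2) +
    stats::rnorm(n, 0, 0.5)
  d
}

# Generator config for fast deterministic cohorts in tests.
test_gen_config <- function(n, seed, ...) {
  generator_config(n_persons = n, seed = seed, include_labs = FALSE,
                   missingness_prob = 0, ...)
}
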