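# Feature vocabulary and encoding for the one-year weight-transition model.
#
# Each questionnaire item contributes indicator features of two kinds:
#   * baseline-interview indicators, firing when the answer at the transition's
#     baseline year equals the feature's level;
#   * predictive-year indicators, firing when the answer at the predictive year
#     equals the level AND (for intention-gated features) the respondent's
#     intention-to-improve level matches the feature's intention column.
# Drinking enters as a numeric frequency/quantity score at both interviews.

#' Lifestyle questionnaire column names
#'
#' The 11 questionnaire items plus the 3-level intention-to-improve indicator,
#' in the order used by the cohort CSV dialect.
#'
#' @return Character vector of column names.
#' @export
lifestyle_columns <- function() {
  c("wants_health_instruction", "heavy_smoker", "drinking_score",
    "fast_walker", "daily_activity_1h", "exercise_2x30min",
    "skips_breakfast_3x", "eating_speed", "late_supper_3x",
    "snacks_between_meals", "sleeps_well", "intention_level")
}

lifestyle_binary_items <- function() {
  c("wants_health_instruction", "heavy_smoker", "fast_walker",
    "daily_activity_1h", "exercise_2x30min", "skips_breakfast_3x",
    "late_supper_3x", "snacks_between_meals", "sleeps_well")
}

#' Laboratory measurement column names
#' @return Character vector of the optional lab columns.
#' @export
lab_columns <- function() {
  c("waist_cm", "SBP", "DBP", "HbA1c", "TG", "HDL_C", "LDL_C",
    "FBG", "AST", "ALT", "GGTP")
}

#' Feature vocabulary of the transition model
#'
#' One row per encoded feature: the continuous block (baseline weight, prior
#' one-year weight difference, height, age, sex, drinking scores) and every
#' questionnaire indicator, identified by item, interview (`baseline` or
#' `predictive`), firing level, and (where applicable) intention column.
#'
#' @return A tibble with columns `feature`, `kind`, `item`, `when`, `level`,
#'   `intent`.
#' @export
feature_vocabulary <- function() {
  cont <- tibble::tibble(
    feature = c("weight_baseline", "weight_diff", "height_baseline",
                "age_baseline", "sex_male", "drinking_base", "drinking_pred"),
    kind = "continuous",
    item = c(NA, NA, NA, NA, NA, "drinking_score", "drinking_score"),
    when = c(NA, NA, NA, NA, NA, "baseline", "predictive"),
    level = NA_character_,
    intent = NA_integer_
  )
  base_ind <- tibble::tribble(
    ~item, ~level,
    "wants_health_instruction", "no",
    "heavy_smoker", "no",
    "fast_walker", "no",
    "daily_activity_1h", "no",
    "exercise_2x30min", "no",
    "skips_breakfast_3x", "yes",
    "eating_speed", "quicker",
    "eating_speed", "normal",
    "late_supper_3x", "yes",
    "snacks_between_meals", "yes",
    "sleeps_well", "no"
  )
  base_ind <- tibble::tibble(
    feature = paste0(base_ind$item, "_base_", base_ind$level),
    kind = "indicator", item = base_ind$item, when = "baseline",
    level = base_ind$level, intent = NA_integer_
  )
  pred_plain <- tibble::tibble(
    feature = "wants_health_instruction_pred_yes",
    kind = "indicator", item = "wants_health_instruction",
    when = "predictive", level = "yes", intent = NA_integer_
  )
  pred_spec <- tibble::tribble(
    ~item, ~level, ~intents,
    "heavy_smoker", "no", list(1:3),
    "fast_walker", "yes", list(1:3),
    "daily_activity_1h", "yes", list(1:3),
    "exercise_2x30min", "yes", list(1:3),
    "exercise_2x30min", "no", list(c(1L, 3L)),
    "skips_breakfast_3x", "no", list(1:3),
    "eating_speed", "normal", list(1:3),
    "eating_speed", "slower", list(1:3),
    "late_supper_3x", "no", list(1:3),
    "snacks_between_meals", "no", list(1:3),
    "sleeps_well", "yes", list(1:3)
  )
  pred_int <- do.call(rbind, lapply(seq_len(nrow(pred_spec)), function(i) {
    ints <- pred_spec$intents[[i]][[1]]
    tibble::tibble(
      feature = paste0(pred_spec$item[i], "_pred_", pred_spec$level[i], "_i", ints),
      kind = "indicator", item = pred_spec$item[i], when = "predictive",
      level = pred_spec$level[i], intent = as.integer(ints)
    )
  }))
  rbind(cont, base_ind, pred_plain, pred_int)
}

# answers: character vector; returns "yes"/"no"/eating-speed levels unchanged,
# validating the domain
check_lifestyle_frame <- function(ls, role) {
  need <- lifestyle_columns()
  miss <- setdiff(need, names(ls))
  if (length(miss)) {
    stop_domain("lifestyle profile (", role, ") is missing item(s): ",
                paste(miss, collapse = ", "))
  }
  for (col in need) {
    if (anyNA(ls[[col]])) {
      stop_domain("lifestyle profile (", role, ") has missing answers for item: ", col)
    }
  }
  invisible(ls)
}

# Vectorised encoder: all arguments length n (lifestyle frames n rows).
# Returns an n x nrow(vocab) numeric matrix with vocabulary column names.
encode_feature_matrix <- function(weight_baseline, weight_diff, height_cm,
                                  age_years, sex, lifestyle_base,
                                  lifestyle_pred, vocab = feature_vocabulary()) {
  n <- length(weight_baseline)
  check_lifestyle_frame(lifestyle_base, "baseline interview")
  check_lifestyle_frame(lifestyle_pred, "predictive-year interview")
  sex_male <- if (is.numeric(sex)) as.numeric(sex) else as.numeric(sex == "male")
  X <- matrix(0, nrow = n, ncol = nrow(vocab),
              dimnames = list(NULL, vocab$feature))
  X[, "weight_baseline"] <- weight_baseline
  X[, "weight_diff"] <- weight_diff
  X[, "height_baseline"] <- height_cm
  X[, "age_baseline"] <- age_years
  X[, "sex_male"] <- sex_male
  X[, "drinking_base"] <- as.numeric(lifestyle_base$drinking_score)
  X[, "drinking_pred"] <- as.numeric(lifestyle_pred$drinking_score)
  ind <- vocab[vocab$kind == "indicator", ]
  intent_pred <- as.integer(lifestyle_pred$intention_level)
  for (i in seq_len(nrow(ind))) {
    src <- if (ind$when[i] == "baseline") lifestyle_base else lifestyle_pred
    fire <- as.character(src[[ind$item[i]]]) == ind$level[i]
    if (!is.na(ind$intent[i])) fire <- fire & intent_pred == ind$intent[i]
    X[, ind$feature[i]] <- as.numeric(fire)
  }
  X
}

#' Encode the feature vector of one weight transition
#'
#' Builds the model's explanatory variables from the baseline-year record, the
#' prior-year record (for the weight-difference covariate) and the
#' predictive-year lifestyle profile. Indicators fire only when the answer
#' matches the feature's level, and intention-gated predictive-year indicators
#' additionally require the matching intention-to-improve level.
#'
#' @param record_t One-row data frame for the baseline year (columns `weight_kg`,
#'   `height_cm`, `age`, `sex`, and the lifestyle columns).
#' @param record_t_minus_1 One-row data frame for the prior year (needs `weight_kg`).
#' @param lifestyle_pred One-row data frame with the predictive-year lifestyle
#'   answers (see [lifestyle_columns()]).
#' @return Named numeric vector over [feature_vocabulary()].
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_persons = 2, seed = 1))
#' r0 <- cohort[cohort$person_id == 1 & cohort$year_index == 0, ]
#' rm1 <- cohort[cohort$person_id == 1 & cohort$year_index == -1, ]
#' r1 <- cohort[cohort$person_id == 1 & cohort$year_index == 1, ]
#' fv <- encode_features(r0, rm1, r1)
encode_features <- function(record_t, record_t_minus_1, lifestyle_pred) {
  stopifnot(nrow(record_t) == 1L, nrow(record_t_minus_1) == 1L,
            nrow(lifestyle_pred) == 1L)
  if (is.na(record_t$weight_kg) || is.na(record_t_minus_1$weight_kg)) {
    stop_domain("weights at the baseline and prior year must both be present")
  }
  subset_ls <- function(d) d[, intersect(lifestyle_columns(), names(d)), drop = FALSE]
  X <- encode_feature_matrix(
    weight_baseline = record_t$weight_kg,
    weight_diff = record_t$weight_kg - record_t_minus_1$weight_kg,
    height_cm = record_t$height_cm,
    age_years = record_t$age,
    sex = record_t$sex,
    lifestyle_base = subset_ls(record_t),
    lifestyle_pred = subset_ls(lifestyle_pred)
  )
  drop(X[1L, ])
}

#' Build the one-year transition table from a longitudinal cohort
#'
#' Stacks the three observed transitions (year 0 to 1, 1 to 2, 2 to 3) of every
#' complete-case person into one regression table: gate variables (baseline
#' BMI, age, sex), the encoded feature vocabulary, optional baseline labs as
#' additional candidate predictors, and the next-year weight target.
#'
#' @param cohort Cohort tibble in the package's long per-person-per-year layout.
#' @param include_labs Offer baseline lab values as candidate predictors.
#' @return A tibble; attribute `"feature_names"` lists the predictor columns.
#' @export
encode_transitions <- function(cohort, include_labs = TRUE) {
  cohort <- cohort[order(cohort$person_id, cohort$year_index), ]
  years <- split(cohort, cohort$year_index)
  need <- as.character(c(-1, 0, 1, 2, 3))
  if (!all(need %in% names(years))) {
    stop_domain("cohort must contain year_index -1..3 for every person")
  }
  ids <- years[["0"]]$person_id
  for (y in need) {
    if (!identical(years[[y]]$person_id, ids)) {
      stop_domain("every person must have exactly one record per year -1..3")
    }
  }
  labs <- intersect(lab_columns(), names(cohort))
  if (!include_labs) labs <- character(0)
  out <- vector("list", 3L)
  for (t in 0:2) {
    yb <- years[[as.character(t)]]
    yp <- years[[as.character(t - 1)]]
    yn <- years[[as.character(t + 1)]]
    X <- encode_feature_matrix(
      weight_baseline = yb$weight_kg,
      weight_diff = yb$weight_kg - yp$weight_kg,
      height_cm = yb$height_cm,
      age_years = yb$age,
      sex = yb$sex,
      lifestyle_base = yb[, lifestyle_columns(), drop = FALSE],
      lifestyle_pred = yn[, lifestyle_columns(), drop = FALSE]
    )
    tab <- tibble::tibble(
      person_id = ids,
      step = t + 1L,
      bmi_baseline = compute_bmi(yb$height_cm, yb$weight_kg)
    )
    tab <- cbind(tab, tibble::as_tibble(X))
    if (length(labs)) {
      yl <- years[["0"]]
      tab <- cbind(tab, tibble::as_tibble(as.data.frame(yl[, labs, drop = FALSE])))
    }
    tab$next_weight <- yn$weight_kg
    out[[t + 1L]] <- tab
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  attr(res, "feature_names") <- c(feature_vocabulary()$feature, labs)
  res
}
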