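# Longitudinal checkup-record handling: BMI, complete-case filtering,
# learning/validation splitting, cohort-comparison statistics, CSV IO.

#' Body mass index
#'
#' @param height_cm Height in centimetres, positive.
#' @param weight_kg Weight in kilograms, positive.
#' @return BMI in kg/m^2 (unrounded; round only for display).
#' @export
#' @examples
#' compute_bmi(170.8, 68.3)
compute_bmi <- function(height_cm, weight_kg) {
  ok <- !is.na(height_cm) & !is.na(weight_kg)
  if (any(height_cm[ok] <= 0) || any(weight_kg[ok] <= 0)) {
    stop_domain("height_cm and weight_kg must be positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' Default required fields for complete-case filtering
#'
#' Weight in every used year (-1..3), the person-constant covariates, and the
#' full lifestyle questionnaire in the interview years (0..3). Labs are not
#' required because the published formulas select none.
#'
#' @return Named list mapping field name to the year indices in which it must
#'   be present (`NULL` = any year).
#' @export
default_required_fields <- function() {
  fields <- c(list(weight_kg = -1:3, height_cm = NULL, age = NULL, sex = NULL),
              stats::setNames(rep(list(0:3), length(lifestyle_columns())),
                              lifestyle_columns()))
  fields
}

#' Complete-case filtering of a longitudinal cohort
#'
#' Retention is all-or-nothing per person: a person is kept only if every
#' required field is present in every year in which it is used.
#'
#' @param records Cohort tibble (long layout, one row per person-year).
#' @param required_fields Named list as returned by
#'   [default_required_fields()]; a plain character vector is interpreted as
#'   "required in every year".
#' @return List with `records` (retained rows) and `n_excluded` (persons dropped).
#' @export
filter_complete_cases <- function(records, required_fields = default_required_fields()) {
  if (is.character(required_fields)) {
    required_fields <- stats::setNames(rep(list(NULL), length(required_fields)),
                                       required_fields)
  }
  if (!length(required_fields)) stop_domain("required_fields must be non-empty")
  if (!nrow(records)) return(list(records = records, n_excluded = 0L))
  ids <- unique(records$person_id)
  bad <- rep(FALSE, length(ids))
  names(bad) <- as.character(ids)
  for (field in names(required_fields)) {
    if (!field %in% names(records)) {
      stop_domain("required field not present in records: ", field)
    }
    yrs <- required_fields[[field]]
    rows <- if (is.null(yrs)) rep(TRUE, nrow(records)) else records$year_index %in% yrs
    miss <- rows & is.na(records[[field]])
    if (any(miss)) {
      bad[as.character(unique(records$person_id[miss]))] <- TRUE
    }
  }
  drop_ids <- ids[bad]
  list(records = records[!records$person_id %in% drop_ids, , drop = FALSE],
       n_excluded = length(drop_ids))
}

#' Person-level learning/validation split
#'
#' @param records Cohort tibble.
#' @param n_learning,n_validation Person counts for the two disjoint sets.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `learning` and `validation` cohort tibbles.
#' @export
split_learning_validation <- function(records, n_learning, n_validation, seed) {
  ids <- unique(records$person_id)
  if (n_learning + n_validation > length(ids)) {
    stop_domain("requested split (", n_learning, " + ", n_validation,
                ") exceeds the ", length(ids), " available persons")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  picked <- sample(ids, n_learning + n_validation)
  learn_ids <- picked[seq_len(n_learning)]
  valid_ids <- picked[n_learning + seq_len(n_validation)]
  list(learning = records[records$person_id %in% learn_ids, , drop = FALSE],
       validation = records[records$person_id %in% valid_ids, , drop = FALSE])
}

#' Baseline cohort comparison (Table-1 style)
#'
#' Compares two cohorts variable by variable at a chosen year: continuous
#' variables with a two-sample t-test (Student by default, Welch optionally),
#' categorical variables with a chi-squared test (no continuity correction by
#' default, matching the plain chi-squared statistic).
#'
#' @param a,b Cohort tibbles (or any data frames with the listed variables).
#' @param variables Character vector of column names to compare.
#' @param year_index Year at which to take each person's value (`NULL` = use
#'   rows as given).
#' @param welch Use the Welch (unequal-variance) t-test.
#' @param correct Apply the Yates continuity correction to 2x2 tables.
#' @return A tibble with one row per variable: summaries, test, statistic,
#'   p-value. Zero-variance continuous variables are flagged (`NA` statistic),
#'   not an error.
#' @export
compare_cohorts <- function(a, b, variables, year_index = 0,
                            welch = FALSE, correct = FALSE) {
  if (!nrow(a) || !nrow(b)) stop_domain("both cohorts must be non-empty")
  take <- function(d) {
    if (!is.null(year_index) && "year_index" %in% names(d)) {
      d[d$year_index == year_index, , drop = FALSE]
    } else d
  }
  a <- take(a); b <- take(b)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(a) || !v %in% names(b)) {
      stop_domain("variable not present in both cohorts: ", v)
    }
    xa <- a[[v]]; xb <- b[[v]]
    if (is.numeric(xa)) {
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      summ <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        return(tibble::tibble(variable = v, type = "continuous",
                              summary_a = summ(xa), summary_b = summ(xb),
                              test = "t", statistic = NA_real_,
                              p_value = NA_real_, note = "zero variance"))
      }
      tt <- stats::t.test(xa, xb, var.equal = !welch)
      tibble::tibble(variable = v, type = "continuous",
                     summary_a = summ(xa), summary_b = summ(xb),
                     test = if (welch) "welch-t" else "student-t",
                     statistic = unname(tt$statistic), p_value = tt$p.value,
                     note = NA_character_)
    } else {
      tab <- table(group = rep(c("a", "b"), c(length(xa), length(xb))),
                   value = c(as.character(xa), as.character(xb)))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      top <- function(x) {
        lev <- names(sort(table(x), decreasing = TRUE))[1]
        sprintf("%s: %d (%.0f%%)", lev, sum(x == lev), 100 * mean(x == lev))
      }
      tibble::tibble(variable = v, type = "categorical",
                     summary_a = top(xa), summary_b = top(xb),
                     test = "chi-squared", statistic = unname(ct$statistic),
                     p_value = ct$p.value, note = NA_character_)
    }
  })
  res <- do.call(rbind, rows)
  class(res) <- c("cohort_comparison", class(res))
  res
}

#' Read / write the cohort CSV dialect
#'
#' One row per person-year; columns `person_id, year_index, sex, age,
#' height_cm, weight_kg, <lab columns>, <lifestyle columns>, intention_level`;
#' missing values are empty cells.
#'
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(d)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
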