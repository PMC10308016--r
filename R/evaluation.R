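# Evaluation layer: RMSE, chained-validation protocol, global
# multiple-regression baseline, squared-error model comparison, and
# parameter-recovery diagnostics against a known generative model.

#' Root mean square error
#'
#' `sqrt(mean((y_true - y_pred)^2))`.
#'
#' @param y_true,y_pred Numeric vectors of equal length, or a data frame with
#'   columns `y_true` and `y_pred` as the first argument.
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))   # sqrt(25/2)
rmse <- function(y_true, y_pred = NULL) {
  if (is.data.frame(y_true)) {
    y_pred <- y_true$y_pred
    y_true <- y_true$y_true
  }
  if (!length(y_true)) stop_domain("rmse of an empty set is undefined")
  if (length(y_true) != length(y_pred)) stop_domain("length mismatch")
  if (anyNA(y_true) || anyNA(y_pred) || any(!is.finite(c(y_true, y_pred)))) {
    stop_domain("rmse requires finite observed and predicted values")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Global multiple-regression baseline
#'
#' One ordinary-least-squares model over the identical feature encoding, with
#' no gating and no sparsity, packaged as a single-leaf `pwl_model` so it runs
#' through the same chained-trajectory evaluation as the piecewise model.
#' Collinear columns are dropped with a warning.
#'
#' @param transitions Transition table from [encode_transitions()].
#' @return A single-leaf `pwl_model`.
#' @export
fit_multiple_regression <- function(transitions) {
  xy <- extract_xy(transitions)
  f <- stats::lm.fit(cbind(`(intercept)` = 1, xy$X), xy$y)
  co <- f$coefficients
  if (anyNA(co)) {
    warning("dropping collinear column(s): ",
            paste(names(co)[is.na(co)], collapse = ", "))
    co <- co[!is.na(co)]
  }
  leaf <- new_leaf_formula(1L, co[["(intercept)"]],
                           co[setdiff(names(co), "(intercept)")],
                           n = length(xy$y))
  pwl_model(new_leaf_node(1L), list(leaf),
            meta = list(source = "multiple_regression", n_train = length(xy$y)))
}

#' Chained validation of a model on a held-out cohort
#'
#' For every person, predicts years 1..3 by chaining the one-year model from
#' the measured years -1/0, with the predictive-year lifestyle held fixed
#' (default: each person's actual year-1 answers, the protocol in which a
#' person commits to one lifestyle for the whole horizon), and compares
#' against the realised weights. `lifestyle = "observed"` instead feeds each
#' year's actual baseline/predictive profiles through the chain.
#'
#' @param model A `pwl_model`.
#' @param cohort Complete-case validation cohort (years -1..3).
#' @param lifestyle `"fixed"` or `"observed"` (see above).
#' @param reassign_leaf,advance_age Chain options, as in
#'   [predict_trajectory()].
#' @return List: `n`, pooled `rmse`, `rmse_by_horizon`, and the per-person
#'   `squared_errors` matrix (persons x horizons).
#' @export
evaluate_model <- function(model, cohort, lifestyle = c("fixed", "observed"),
                           reassign_leaf = TRUE, advance_age = TRUE) {
  lifestyle <- match.arg(lifestyle)
  cohort <- cohort[order(cohort$person_id, cohort$year_index), ]
  years <- split(cohort, cohort$year_index)
  need <- as.character(-1:3)
  if (!all(need %in% names(years))) stop_domain("cohort must cover years -1..3")
  ids <- years[["0"]]$person_id
  h0 <- years[["0"]]; hm1 <- years[["-1"]]
  state <- data.frame(weight_prev = hm1$weight_kg, weight_base = h0$weight_kg,
                      height_cm = h0$height_cm, age = h0$age,
                      sex_male = as.numeric(h0$sex == "male"))
  for (lc in intersect(lab_columns(), names(cohort))) state[[lc]] <- h0[[lc]]
  prof <- function(y) years[[as.character(y)]][, lifestyle_columns(), drop = FALSE]
  if (lifestyle == "fixed") {
    scen <- prof(1)
    base_profiles <- list(prof(0), scen, scen)
    pred_profiles <- list(scen, scen, scen)
  } else {
    base_profiles <- list(prof(0), prof(1), prof(2))
    pred_profiles <- list(prof(1), prof(2), prof(3))
  }
  W <- chain_forecast(model, state, base_profiles, pred_profiles, 3L,
                      reassign_leaf = reassign_leaf, advance_age = advance_age)
  actual <- cbind(years[["1"]]$weight_kg, years[["2"]]$weight_kg,
                  years[["3"]]$weight_kg)
  se <- (actual - W)^2
  rownames(se) <- ids
  colnames(se) <- paste0("year", 1:3)
  list(n = length(ids),
       rmse = sqrt(mean(se)),
       rmse_by_horizon = sqrt(colMeans(se)),
       squared_errors = se)
}

#' Compare two models' squared prediction errors
#'
#' Two-sample t-test on per-person squared errors: unpaired Student form by
#' default (the conventional test family for such comparisons); a paired test
#' is available and is statistically preferable when both models are scored
#' on the same persons.
#'
#' @param squared_errors_a,squared_errors_b Numeric vectors of per-person
#'   squared errors.
#' @param paired Use the paired t-test.
#' @param welch Unpaired only: use the Welch form.
#' @return List with `statistic`, `p_value`, `test`. Zero variance in both
#'   samples is flagged (`NA` statistic), not an error.
#' @export
compare_models <- function(squared_errors_a, squared_errors_b,
                           paired = FALSE, welch = FALSE) {
  a <- squared_errors_a; b <- squared_errors_b
  if (!length(a) || !length(b)) stop_domain("both error samples must be non-empty")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && (!paired || stats::sd(a - b) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                test = "t", note = "zero variance in both samples"))
  }
  tt <- if (paired) stats::t.test(a, b, paired = TRUE)
        else stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       test = if (paired) "paired-t" else if (welch) "welch-t" else "student-t")
}

# probe set used to match fitted tree regions to a reference model's regions;
# deterministic by construction (regular grid over the clinical ranges)
recovery_probes <- function() {
  g <- expand.grid(bmi = seq(15, 45, by = 0.1), age = 19:91, sex = c(0, 1))
  g
}

#' Parameter-recovery diagnostics against a known generative model
#'
#' Compares a fitted gating-tree model with the model that generated the data:
#' leaf count, gate thresholds matched by region overlap (each fitted gate is
#' paired with the reference boundary whose induced two-way partition it
#' reproduces best over a dense BMI/age/sex probe grid, so the diagnosis is
#' invariant to split order and leaf labels), and per-leaf coefficient errors
#' after matching leaves by probe-region overlap.
#'
#' @param true_model Reference `pwl_model`.
#' @param fitted A `pwl_model` or `hml_fit`.
#' @return A `recovery_report`: `leaf_count`, `leaf_count_match`, `gates`
#'   (role, true/fitted thresholds, absolute error), `leaf_match`,
#'   `coef_errors` (per matched leaf: max absolute coefficient error), and
#'   convenience accessors used by the acceptance analysis
#'   (`weight_coefs`, `weight_diff_coef_leaf1`).
#' @export
recovery_report <- function(true_model, fitted) {
  if (inherits(fitted, "hml_fit")) fitted <- fitted$model
  stopifnot(inherits(true_model, "pwl_model"), inherits(fitted, "pwl_model"))
  vocab_true <- unique(unlist(lapply(true_model$leaves, function(l) names(l$terms))))
  vocab_fit <- unique(unlist(lapply(fitted$leaves, function(l) names(l$terms))))
  if (length(vocab_fit) && !length(intersect(vocab_true, vocab_fit))) {
    stop_domain("the two models share no feature vocabulary")
  }
  pr <- recovery_probes()
  leaf_true <- assign_leaf(pr$bmi, pr$age, pr$sex, true_model)
  leaf_fit <- assign_leaf(pr$bmi, pr$age, pr$sex, fitted)

  # gate-role matching by partition agreement over the probes
  gates_true <- collect_gates(true_model$tree)
  gates_fit <- collect_gates(fitted$tree)
  probe_val <- function(f) switch(f, bmi_baseline = pr$bmi,
                                  age_baseline = pr$age, sex_male = pr$sex)
  gate_rows <- NULL
  if (!is.null(gates_true)) {
    for (i in seq_len(nrow(gates_true))) {
      tf <- gates_true$feature[i]; tt <- gates_true$threshold[i]
      ind_true <- probe_val(tf) >= tt
      fitted_t <- NA_real_
      if (!is.null(gates_fit)) {
        same <- gates_fit[gates_fit$feature == tf, , drop = FALSE]
        if (nrow(same)) {
          agree <- vapply(same$threshold, function(ft) {
            mean((probe_val(tf) >= ft) == ind_true)
          }, numeric(1))
          fitted_t <- same$threshold[which.max(agree)]
        }
      }
      gate_rows <- rbind(gate_rows, data.frame(
        feature = tf, true_threshold = tt, fitted_threshold = fitted_t,
        abs_error = abs(fitted_t - tt), depth = gates_true$depth[i]))
    }
  }

  # leaf matching by maximal probe-region overlap (greedy on overlap counts)
  tab <- table(true = leaf_true, fitted = leaf_fit)
  match_map <- stats::setNames(rep(NA_integer_, length(true_model$leaves)),
                               vapply(true_model$leaves, `[[`, 1L, "id"))
  tb <- as.data.frame(tab, stringsAsFactors = FALSE)
  tb <- tb[order(-tb$Freq), ]
  used_fit <- character(0)
  for (r in seq_len(nrow(tb))) {
    tr <- tb$true[r]; fr <- tb$fitted[r]
    if (is.na(match_map[tr]) && !(fr %in% used_fit) && tb$Freq[r] > 0) {
      match_map[tr] <- as.integer(fr)
      used_fit <- c(used_fit, fr)
    }
  }

  full_vec <- function(leaf, vocab) {
    v <- stats::setNames(numeric(length(vocab)), vocab)
    v[names(leaf$terms)] <- leaf$terms
    v
  }
  vocab_all <- union(vocab_true, vocab_fit)
  fit_ids <- vapply(fitted$leaves, `[[`, 1L, "id")
  coef_rows <- NULL
  weight_coefs <- numeric(0)
  wdiff_leaf1 <- NA_real_
  for (tl in true_model$leaves) {
    fid <- match_map[as.character(tl$id)]
    if (is.na(fid)) next
    fl <- fitted$leaves[[match(fid, fit_ids)]]
    dv <- abs(full_vec(tl, vocab_all) - full_vec(fl, vocab_all))
    coef_rows <- rbind(coef_rows, data.frame(
      true_leaf = tl$id, fitted_leaf = fid,
      max_abs_coef_error = max(dv),
      bias_error = abs(tl$bias - fl$bias)))
    wb <- if ("weight_baseline" %in% names(fl$terms))
            unname(fl$terms["weight_baseline"]) else 0
    weight_coefs <- c(weight_coefs, stats::setNames(wb, tl$id))
    if (tl$id == 1L) {
      wdiff_leaf1 <- if ("weight_diff" %in% names(fl$terms))
                       unname(fl$terms["weight_diff"]) else 0
    }
  }

  structure(list(
    leaf_count = length(fitted$leaves),
    leaf_count_match = length(fitted$leaves) == length(true_model$leaves),
    gates = gate_rows,
    leaf_match = match_map,
    coef_errors = coef_rows,
    weight_coefs = weight_coefs,
    weight_diff_coef_leaf1 = wdiff_leaf1
  ), class = "recovery_report")
}

#' Multi-seed parameter-recovery study
#'
#' The package's primary validation design: for each seed, simulate a cohort
#' from a reference model (default: the published model, noise 1 kg, no
#' missingness so the learner trains on exactly `n_persons` persons), refit
#' the gating tree with [fit_partition()], and summarise recovery across
#' seeds — modal leaf count, median recovered thresholds for each published
#' gate, median baseline-weight coefficient over all matched leaves, and the
#' median weight-difference coefficient of the leaf matched to formula 1.
#'
#' @param seeds Integer vector of generator seeds (one run per seed).
#' @param n_persons Persons per simulated cohort.
#' @param noise_sd_kg Innovation SD of the generator.
#' @param true_model Reference `pwl_model` (default: the published model).
#' @param fit Learner configuration.
#' @return List: `reports` (per-seed `recovery_report`s), `leaf_counts`,
#'   `modal_leaf_count`, `median_thresholds` (named by gate role),
#'   `median_weight_coef`, `median_weight_diff_coef_leaf1`.
#' @export
recovery_study <- function(seeds, n_persons = 20000, noise_sd_kg = 1,
                           true_model = NULL, fit = fit_config()) {
  true_model <- true_model %||% load_published_model()
  reports <- lapply(seeds, function(s) {
    cfg <- generator_config(n_persons = n_persons, seed = s,
                            noise_sd_kg = noise_sd_kg, missingness_prob = 0,
                            ground_truth_model = true_model)
    cohort <- generate_cohort(cfg)
    fitres <- fit_partition(encode_transitions(cohort), fit)
    recovery_report(true_model, fitres)
  })
  leaf_counts <- vapply(reports, `[[`, numeric(1), "leaf_count")
  modal <- as.integer(names(sort(table(leaf_counts), decreasing = TRUE))[1])
  gate_key <- function(g) paste0(g$feature, "_", sprintf("%g", g$true_threshold))
  g1 <- reports[[1]]$gates
  med_thr <- vapply(seq_len(nrow(g1)), function(i) {
    stats::median(vapply(reports, function(r) r$gates$fitted_threshold[i],
                         numeric(1)), na.rm = TRUE)
  }, numeric(1))
  names(med_thr) <- gate_key(g1)
  list(
    reports = reports,
    leaf_counts = leaf_counts,
    modal_leaf_count = modal,
    median_thresholds = med_thr,
    median_weight_coef = stats::median(unlist(lapply(reports, `[[`, "weight_coefs"))),
    median_weight_diff_coef_leaf1 = stats::median(
      vapply(reports, `[[`, numeric(1), "weight_diff_coef_leaf1"), na.rm = TRUE)
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report: fitted", x$leaf_count, "leaves (match:",
      x$leaf_count_match, ")\n")
  if (!is.null(x$gates)) print(x$gates, row.names = FALSE)
  invisible(x)
}
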