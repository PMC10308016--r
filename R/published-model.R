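# The piecewise-linear weight predictor: a binary gating tree over baseline
# BMI / age / sex routing each person to one of several sparse linear leaf
# formulas over the encoded feature vocabulary. The published five-formula
# model ships as a JSON fixture in inst/extdata.

GATE_FEATURES <- c("bmi_baseline", "age_baseline", "sex_male")

new_gate <- function(feature, threshold, left, right) {
  stopifnot(feature %in% GATE_FEATURES)
  list(kind = "gate", feature = feature, threshold = as.numeric(threshold),
       left = left, right = right)
}

new_leaf_node <- function(id) list(kind = "leaf", leaf = as.integer(id))

new_leaf_formula <- function(id, bias, terms, n = NA_integer_) {
  stopifnot(is.numeric(terms), !is.null(names(terms)) || length(terms) == 0L)
  structure(list(id = as.integer(id), bias = as.numeric(bias),
                 terms = terms, n = n),
            class = "leaf_formula")
}

#' Construct a piecewise-linear weight model
#'
#' @param tree Nested gate/leaf node list; every numeric gate sends
#'   `feature >= threshold` to the right child.
#' @param leaves List of leaf formulas (`id`, `bias`, named `terms`).
#' @param meta Optional metadata list (version, source, checksum).
#' @return An object of class `pwl_model`.
#' @export
pwl_model <- function(tree, leaves, meta = list()) {
  ids <- vapply(leaves, function(l) l$id, integer(1))
  tree_ids <- collect_leaf_ids(tree)
  if (!setequal(ids, tree_ids) || anyDuplicated(ids)) {
    stop_domain("leaf ids in the tree and the leaf list must match one-to-one")
  }
  leaves <- leaves[order(ids)]
  structure(list(tree = tree, leaves = leaves, meta = meta), class = "pwl_model")
}

collect_leaf_ids <- function(node) {
  if (node$kind == "leaf") return(node$leaf)
  c(collect_leaf_ids(node$left), collect_leaf_ids(node$right))
}

collect_gates <- function(node, depth = 0L) {
  if (node$kind == "leaf") return(NULL)
  rbind(
    data.frame(feature = node$feature, threshold = node$threshold, depth = depth),
    collect_gates(node$left, depth + 1L),
    collect_gates(node$right, depth + 1L)
  )
}

#' @export
print.pwl_model <- function(x, ...) {
  cat("Piecewise-linear weight model:", length(x$leaves), "leaf formula(s)\n")
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      lf <- x$leaves[[match(node$leaf, vapply(x$leaves, `[[`, 1L, "id"))]]
      cat(pad, "leaf ", node$leaf, ": bias ", format(lf$bias),
          ", ", length(lf$terms), " term(s)\n", sep = "")
    } else {
      cat(pad, node$feature, " >= ", format(node$threshold), "?\n", sep = "")
      show_node(node$left, indent + 1L)
      show_node(node$right, indent + 1L)
    }
  }
  show_node(x$tree, 1L)
  invisible(x)
}

#' @export
print.leaf_formula <- function(x, ...) {
  cat("Leaf formula", x$id, "- bias", format(x$bias), "-",
      length(x$terms), "selected term(s)\n")
  invisible(x)
}

# canonical string -> 32-bit checksum; guards the fixture against coefficient drift
model_checksum <- function(model) {
  leaf_str <- vapply(model$leaves, function(l) {
    o <- order(names(l$terms))
    paste0(l$id, ":", sprintf("%.6f", l$bias), ":",
           paste0(names(l$terms)[o], "=", sprintf("%.6f", l$terms[o]),
                  collapse = ","))
  }, character(1))
  gate_str <- ""
  g <- collect_gates(model$tree)
  if (!is.null(g)) {
    gate_str <- paste0(g$feature, "@", sprintf("%.6f", g$threshold), collapse = ";")
  }
  hash32(paste(gate_str, paste(leaf_str, collapse = "|"), sep = "#"))
}

node_to_json <- function(node) {
  if (node$kind == "leaf") return(list(leaf = node$leaf))
  list(feature = node$feature, threshold = node$threshold,
       left = node_to_json(node$left), right = node_to_json(node$right))
}

node_from_json <- function(node) {
  if (!is.null(node$leaf)) return(new_leaf_node(node$leaf))
  if (is.null(node$feature) || is.null(node$threshold)) {
    stop_domain("model JSON: gate node must carry 'feature' and 'threshold'")
  }
  new_gate(node$feature, node$threshold,
           node_from_json(node$left), node_from_json(node$right))
}

#' Serialise / deserialise a model as JSON
#'
#' The JSON schema is shared by the published fixture and fitted models, so
#' downstream prediction and evaluation code is model-agnostic. Round-trips
#' are lossless on all coefficients.
#'
#' @param model A `pwl_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    tree = node_to_json(model$tree),
    leaves = lapply(model$leaves, function(l) {
      list(id = l$id, bias = l$bias, terms = as.list(l$terms))
    }),
    meta = utils::modifyList(model$meta, list(checksum = model_checksum(model)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns the `pwl_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$tree) || is.null(obj$leaves)) {
    stop_domain("model JSON: 'tree' and 'leaves' entries are required")
  }
  leaves <- lapply(obj$leaves, function(l) {
    if (is.null(l$id) || is.null(l$bias)) {
      stop_domain("model JSON: leaf entry missing 'id' or 'bias'")
    }
    terms <- unlist(l$terms)
    if (is.null(terms)) terms <- stats::setNames(numeric(0), character(0))
    if (!is.numeric(terms)) {
      stop_domain("model JSON: non-numeric coefficient in leaf ", l$id)
    }
    new_leaf_formula(l$id, l$bias, terms)
  })
  model <- pwl_model(node_from_json(obj$tree), leaves,
                     meta = lapply(obj$meta %||% list(), identity))
  if (!is.null(model$meta$checksum)) {
    if (model_checksum(model) != as.integer(model$meta$checksum)) {
      stop_domain("model JSON failed its checksum: coefficients differ from ",
                  "the values recorded at serialisation time")
    }
  }
  model
}

#' Load the published five-formula model
#'
#' Reads the packaged machine-readable transcription of the published gating
#' tree (BMI split at 29.93, BMI split at 23.44, sex split, age split at the
#' 24/25-year boundary) and the five sparse leaf formulas, and verifies the
#' stored checksum so any coefficient drift in the fixture is rejected.
#'
#' @param path Fixture path; defaults to the packaged fixture.
#' @return A `pwl_model` with five leaves.
#' @export
load_published_model <- function(path = system.file("extdata", "published_model.json",
                                                    package = "weightcast")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_domain("published-model fixture not found")
  }
  model <- read_model_json(path)
  if (is.null(model$meta$checksum)) {
    stop_domain("published-model fixture must carry a checksum")
  }
  model
}

#' Route persons to leaf formulas
#'
#' Deterministic gate traversal: numeric gates send `value >= threshold` to
#' the right (so the BMI thresholds are inclusive on the high side), and the
#' sex gate routes males right.
#'
#' @param bmi,age_years,sex Vectors (recycled to common length); `sex` may be
#'   `"male"`/`"female"` or 0/1.
#' @param model A `pwl_model` (or a bare tree node).
#' @return Integer vector of leaf ids.
#' @export
#' @examples
#' m <- load_published_model()
#' assign_leaf(c(31, 25, 20), c(50, 24, 30), c("male", "male", "female"), m)
assign_leaf <- function(bmi, age_years, sex, model) {
  tree <- if (inherits(model, "pwl_model")) model$tree else model
  n <- max(length(bmi), length(age_years), length(sex))
  vals <- list(
    bmi_baseline = rep_len(as.numeric(bmi), n),
    age_baseline = rep_len(as.numeric(age_years), n),
    sex_male = rep_len(if (is.numeric(sex)) as.numeric(sex)
                       else as.numeric(sex == "male"), n)
  )
  if (any(vals$bmi_baseline <= 0, na.rm = TRUE)) stop_domain("bmi must be positive")
  out <- integer(n)
  walk <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$kind == "leaf") {
      out[idx] <<- node$leaf
      return(invisible())
    }
    right <- vals[[node$feature]][idx] >= node$threshold
    walk(node$left, idx[!right])
    walk(node$right, idx[right])
  }
  walk(tree, seq_len(n))
  out
}

#' One-year prediction from a leaf formula
#'
#' `bias + sum(coefficient * feature)` over the leaf's selected terms;
#' unselected features contribute exactly zero.
#'
#' @param fv Named numeric feature vector (or matrix with named columns).
#' @param leaf A `leaf_formula`.
#' @return Predicted next-year weight (kg).
#' @export
predict_one_year <- function(fv, leaf) {
  if (is.matrix(fv)) {
    miss <- setdiff(names(leaf$terms), colnames(fv))
    if (length(miss)) stop_domain("feature vector lacks term(s): ",
                                  paste(miss, collapse = ", "))
    if (!length(leaf$terms)) return(rep(leaf$bias, nrow(fv)))
    # row-wise accumulation keeps results independent of the batch size
    Z <- fv[, names(leaf$terms), drop = FALSE] *
      rep(leaf$terms, each = nrow(fv))
    unname(leaf$bias + rowSums(Z))
  } else {
    miss <- setdiff(names(leaf$terms), names(fv))
    if (length(miss)) stop_domain("feature vector lacks term(s): ",
                                  paste(miss, collapse = ", "))
    unname(leaf$bias + sum(leaf$terms * fv[names(leaf$terms)]))
  }
}

# Vectorised one-step chain over persons. state: data frame with columns
# weight_prev, weight_base, height_cm, age, sex_male, plus optional extra
# covariate columns (labs) used only if a leaf selected them.
chain_step <- function(model, state, lifestyle_base, lifestyle_pred,
                       reassign_bmi = NULL) {
  X <- encode_feature_matrix(
    weight_baseline = state$weight_base,
    weight_diff = state$weight_base - state$weight_prev,
    height_cm = state$height_cm,
    age_years = state$age,
    sex = state$sex_male,
    lifestyle_base = lifestyle_base,
    lifestyle_pred = lifestyle_pred
  )
  extra <- setdiff(names(state),
                   c("weight_prev", "weight_base", "height_cm", "age", "sex_male"))
  if (length(extra)) X <- cbind(X, as.matrix(state[, extra, drop = FALSE]))
  bmi <- reassign_bmi %||% compute_bmi(state$height_cm, state$weight_base)
  leaf_id <- assign_leaf(bmi, state$age, state$sex_male, model)
  pred <- numeric(nrow(state))
  for (lf in model$leaves) {
    idx <- which(leaf_id == lf$id)
    if (length(idx)) pred[idx] <- predict_one_year(X[idx, , drop = FALSE], lf)
  }
  list(pred = pred, leaf_id = leaf_id)
}

# Chained multi-year forecast shared by prediction and synthetic generation.
# base_profiles / pred_profiles: lists of length `horizon` of lifestyle frames
# (row-aligned with `state`). noise: matrix n x horizon added to each realised
# step (zero for pure prediction). Returns n x horizon weight matrix.
chain_forecast <- function(model, state, base_profiles, pred_profiles, horizon,
                           reassign_leaf = TRUE, advance_age = TRUE,
                           noise = NULL) {
  n <- nrow(state)
  W <- matrix(NA_real_, n, horizon)
  bmi0 <- compute_bmi(state$height_cm, state$weight_base)
  st <- state
  for (k in seq_len(horizon)) {
    step <- chain_step(model, st, base_profiles[[k]], pred_profiles[[k]],
                       reassign_bmi = if (reassign_leaf) NULL else bmi0)
    w_new <- step$pred
    if (!is.null(noise)) w_new <- w_new + noise[, k]
    W[, k] <- w_new
    st$weight_prev <- st$weight_base
    st$weight_base <- w_new
    if (advance_age) st$age <- st$age + 1
  }
  W
}

person_state <- function(history) {
  need <- c("person_id", "year_index", "sex", "height_cm", "weight_kg", "age")
  miss <- setdiff(need, names(history))
  if (length(miss)) stop_domain("history lacks column(s): ",
                                paste(miss, collapse = ", "))
  hm1 <- history[history$year_index == -1, , drop = FALSE]
  h0 <- history[history$year_index == 0, , drop = FALSE]
  if (nrow(hm1) != 1L || nrow(h0) != 1L ||
      is.na(hm1$weight_kg) || is.na(h0$weight_kg)) {
    stop_domain("history must contain measured weights at years -1 and 0")
  }
  st <- data.frame(weight_prev = hm1$weight_kg, weight_base = h0$weight_kg,
                   height_cm = h0$height_cm, age = h0$age,
                   sex_male = as.numeric(h0$sex == "male"))
  labs <- intersect(lab_columns(), names(history))
  for (lc in labs) st[[lc]] <- h0[[lc]]  # baseline labs, held fixed in the chain
  list(
    state = st,
    baseline_profile = h0[, lifestyle_columns(), drop = FALSE],
    person_id = h0$person_id,
    measured = c(hm1$weight_kg, h0$weight_kg)
  )
}

#' Chained multi-year weight forecast for one person
#'
#' Iterates the one-year model: each year's prediction becomes the next year's
#' baseline weight and the weight-difference covariate is updated to
#' (predicted - previous). The predictive-year lifestyle is held fixed at the
#' scenario for every step, mirroring a person committing to a lifestyle for
#' the whole horizon; from the second step on the scenario also serves as the
#' baseline interview. By default the gate is re-evaluated each year with the
#' updated BMI; `reassign_leaf = FALSE` freezes the baseline leaf.
#'
#' @param history Data frame with the person's year -1 and 0 records
#'   (measured weights, height, age, sex, year-0 lifestyle columns).
#' @param lifestyle_scenario One-row data frame of predictive-year lifestyle
#'   answers (see [lifestyle_columns()]).
#' @param model A `pwl_model`.
#' @param horizon Number of years to forecast (>= 1, default 3).
#' @param reassign_leaf Re-evaluate gates each year using updated BMI.
#' @param advance_age Advance age by one year per step (`FALSE` freezes age).
#' @param scenario Label stored on the trajectory.
#' @return A `prediction_trajectory`: measured weights (years -1, 0) plus the
#'   chained predictions (years 1..horizon).
#' @export
predict_trajectory <- function(history, lifestyle_scenario, model, horizon = 3,
                               reassign_leaf = TRUE, advance_age = TRUE,
                               scenario = "scenario") {
  if (!is.numeric(horizon) || horizon < 1) stop_domain("horizon must be >= 1")
  horizon <- as.integer(horizon)
  ps <- person_state(history)
  scen <- lifestyle_scenario[, lifestyle_columns(), drop = FALSE]
  base_profiles <- c(list(ps$baseline_profile),
                     rep(list(scen), max(0L, horizon - 1L)))
  pred_profiles <- rep(list(scen), horizon)
  W <- chain_forecast(model, ps$state, base_profiles, pred_profiles, horizon,
                      reassign_leaf = reassign_leaf, advance_age = advance_age)
  structure(list(person_id = ps$person_id, measured = ps$measured,
                 predicted = drop(W[1L, ]), scenario = scenario,
                 horizon = horizon),
            class = "prediction_trajectory")
}

#' @export
print.prediction_trajectory <- function(x, ...) {
  cat("Weight trajectory for person", x$person_id,
      "under scenario '", x$scenario, "'\n", sep = " ")
  cat("  measured (years -1, 0): ", paste(sprintf("%.2f", x$measured),
                                          collapse = ", "), "\n")
  cat("  predicted (years 1..", x$horizon, "): ",
      paste(sprintf("%.2f", x$predicted), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare two lifestyle scenarios for the same person
#'
#' Runs [predict_trajectory()] twice from identical measured history under two
#' candidate lifestyle commitments, enabling what-if plots of future weight.
#'
#' @inheritParams predict_trajectory
#' @param scenario_a,scenario_b One-row lifestyle data frames.
#' @param labels Character labels for the two trajectories.
#' @return List of two `prediction_trajectory` objects.
#' @export
scenario_compare <- function(history, scenario_a, scenario_b, model,
                             horizon = 3, labels = c("A", "B"), ...) {
  same <- isTRUE(all.equal(scenario_a[, lifestyle_columns(), drop = FALSE],
                           scenario_b[, lifestyle_columns(), drop = FALSE],
                           check.attributes = FALSE))
  if (same) warning("the two scenarios are identical; trajectories will coincide")
  list(
    predict_trajectory(history, scenario_a, model, horizon,
                       scenario = labels[1], ...),
    predict_trajectory(history, scenario_b, model, horizon,
                       scenario = labels[2], ...)
  )
}
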