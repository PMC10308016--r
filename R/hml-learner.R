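# Heterogeneous-mixture learner: greedy top-down search for a gating tree
# whose leaves are sparse linear regressions selected by a BIC-like penalised
# Gaussian log-likelihood with component-local sample size. The split search
# works entirely on sufficient statistics (cross-product matrices of
# [1, X, y]), accumulated per threshold bin, so that every candidate split is
# scored by two exact forward-selection fits without touching the raw rows.

#' Learner configuration
#'
#' @param max_depth Maximum gating-tree depth (root = depth 0).
#' @param min_leaf_n Minimum rows per leaf; split candidates producing a
#'   smaller child are infeasible.
#' @param gate_features Candidate gate variables; the default restricts gates
#'   to the three variables a clinician would stratify on (baseline BMI, age,
#'   sex). `gate_features = "all"` opens every encoded feature (exploratory).
#' @param threshold_grid Number of empirical quantiles scanned per numeric
#'   gate; the accepted split is then refined by an exact scan between the
#'   bracketing grid points.
#' @param split_penalty `"bic"` (log(n_local) per parameter, default) or
#'   `"aic"`.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   recorded for provenance).
#' @return A `fit_config` list.
#' @export
fit_config <- function(max_depth = 3L, min_leaf_n = 200L,
                       gate_features = c("bmi_baseline", "age_baseline", "sex_male"),
                       threshold_grid = 64L, split_penalty = c("bic", "aic"),
                       seed = 1L) {
  split_penalty <- match.arg(split_penalty)
  stopifnot(max_depth >= 0, min_leaf_n >= 2, threshold_grid >= 1)
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf_n = as.integer(min_leaf_n),
                 gate_features = gate_features,
                 threshold_grid = as.integer(threshold_grid),
                 split_penalty = split_penalty,
                 seed = as.integer(seed)),
            class = "fit_config")
}

penalty_per_param <- function(n, config) {
  if (config$split_penalty == "aic") 1 else log(n) / 2
}

# Gaussian log-likelihood of an OLS leaf, penalised per selected parameter
# (k slopes + intercept + variance).
leaf_criterion <- function(rss, n, k, config) {
  rss <- max(rss, n * 1e-10)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  ll - penalty_per_param(n, config) * (k + 2)
}

# --- sweep-operator forward selection on an SSCP matrix -------------------

sweep_pivot <- function(M, k) {
  d <- M[k, k]
  colk <- M[, k]
  M <- M - outer(colk, M[k, ]) / d
  M[, k] <- colk / d
  M[k, ] <- colk / d
  M[k, k] <- -1 / d
  M
}

# M: SSCP of [intercept, features, y]; rows/cols named. Forward-selects
# features while the penalised criterion improves. Returns coefficients,
# RSS, criterion value, selected set, and skipped (collinear) candidates.
forward_select_sscp <- function(M, n, config, feature_idx = NULL) {
  p_all <- nrow(M)
  yi <- p_all
  feature_idx <- feature_idx %||% seq(2L, p_all - 1L)
  diag0 <- diag(M)
  M <- sweep_pivot(M, 1L)                      # intercept always in
  rss <- M[yi, yi]
  pen <- penalty_per_param(n, config)
  selected <- integer(0)
  dropped <- character(0)
  candidates <- feature_idx
  repeat {
    if (!length(candidates)) break
    dj <- diag(M)[candidates]
    ok <- dj > pmax(1e-10 * diag0[candidates], 1e-12)
    gain_rss <- rep(-Inf, length(candidates))
    gain_rss[ok] <- M[candidates[ok], yi]^2 / dj[ok]
    new_rss <- pmax(rss - gain_rss, n * 1e-10)
    dcrit <- n / 2 * (log(max(rss, n * 1e-10)) - log(new_rss)) - pen
    dcrit[!ok] <- -Inf
    best <- which.max(dcrit)
    if (dcrit[best] <= 0) break
    j <- candidates[best]
    M <- sweep_pivot(M, j)
    rss <- M[yi, yi]
    selected <- c(selected, j)
    candidates <- candidates[-best]
    bad <- candidates[diag(M)[candidates] <= pmax(1e-10 * diag0[candidates[seq_along(candidates)]], 1e-12)]
    if (length(bad)) dropped <- union(dropped, rownames(M)[bad])
  }
  coefs <- if (length(selected)) stats::setNames(M[selected, yi], rownames(M)[selected])
           else stats::setNames(numeric(0), character(0))
  list(bias = M[1L, yi], coefs = coefs, rss = rss,
       criterion = leaf_criterion(rss, n, length(selected), config),
       selected = sort(selected), dropped = dropped)
}

sscp_of <- function(X, y) {
  A <- cbind(`(intercept)` = 1, X, .y = y)
  crossprod(A)
}

#' Fit one sparse linear leaf formula
#'
#' Ordinary least squares with forward selection: features enter one at a time
#' while the penalised Gaussian log-likelihood criterion improves; unselected
#' features have an exact zero coefficient. Collinear candidates are skipped
#' and recorded in the `dropped` attribute.
#'
#' @param features Numeric matrix or data frame of candidate predictors
#'   (named columns).
#' @param target Numeric response (next-year weight).
#' @param config A [fit_config()].
#' @param id Leaf id stored on the result.
#' @return A `leaf_formula` (bias, selected `terms`, `n`), with attributes
#'   `rss`, `criterion` and `dropped`.
#' @export
fit_leaf_regression <- function(features, target, config = fit_config(), id = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < config$min_leaf_n) {
    stop_domain("leaf has ", n, " rows; min_leaf_n is ", config$min_leaf_n)
  }
  if (anyNA(X) || anyNA(target)) stop_domain("leaf fit requires complete cases")
  fs <- forward_select_sscp(sscp_of(X, target), n, config)
  lf <- new_leaf_formula(id, fs$bias, fs$coefs, n = n)
  attr(lf, "rss") <- fs$rss
  attr(lf, "criterion") <- fs$criterion
  attr(lf, "dropped") <- fs$dropped
  lf
}

# --- split search ----------------------------------------------------------

# Candidate thresholds for a numeric gate: midpoints between consecutive
# distinct empirical quantiles (every threshold separates data actually
# observed on both sides). A 0/1 gate yields the single threshold 0.5.
gate_thresholds <- function(x, grid) {
  ux <- sort(unique(x))
  if (length(ux) <= 1L) return(numeric(0))
  if (length(ux) == 2L) return(mean(ux))
  qs <- unique(stats::quantile(x, probs = seq_len(grid) / (grid + 1),
                               type = 1, names = FALSE))
  qs <- sort(unique(qs))
  if (length(qs) < 2L) return(numeric(0))
  (qs[-1] + qs[-length(qs)]) / 2
}

extract_xy <- function(transitions) {
  feats <- attr(transitions, "feature_names") %||%
    setdiff(names(transitions), c("person_id", "step", "bmi_baseline", "next_weight"))
  X <- as.matrix(transitions[, feats, drop = FALSE])
  list(X = X, y = transitions$next_weight,
       gates = list(bmi_baseline = transitions$bmi_baseline,
                    age_baseline = transitions$age_baseline,
                    sex_male = transitions$sex_male),
       features = feats)
}

# Score all thresholds of one gate feature at a node via cumulative bin SSCPs.
# Returns data.frame(threshold, gain, n_left, n_right) for feasible candidates.
score_thresholds <- function(A, idx, gx, thresholds, parent_crit, n_node, config) {
  if (!length(thresholds)) return(NULL)
  bin <- findInterval(gx, thresholds, left.open = FALSE) + 1L
  # bin b = rows with x in [t_{b-1}, t_b); row goes right iff x >= t  ->
  # left set of threshold t_j = bins 1..j
  m <- length(thresholds) + 1L
  p <- ncol(A)
  cums <- array(0, dim = c(p, p, m))
  counts <- tabulate(bin, nbins = m)
  acc <- matrix(0, p, p)
  rows_by_bin <- split(idx, factor(bin, levels = seq_len(m)))
  for (b in seq_len(m)) {
    rb <- rows_by_bin[[b]]
    if (length(rb)) acc <- acc + crossprod(A[rb, , drop = FALSE])
    cums[, , b] <- acc
  }
  total <- acc
  n_cum <- cumsum(counts)
  out <- NULL
  for (j in seq_along(thresholds)) {
    nl <- n_cum[j]; nr <- n_node - nl
    if (nl < config$min_leaf_n || nr < config$min_leaf_n) next
    ML <- cums[, , j]
    MR <- total - ML
    dimnames(ML) <- dimnames(MR) <- dimnames(total)
    fl <- forward_select_sscp(ML, nl, config)
    fr <- forward_select_sscp(MR, nr, config)
    out <- rbind(out, data.frame(threshold = thresholds[j],
                                 gain = fl$criterion + fr$criterion - parent_crit,
                                 n_left = nl, n_right = nr))
  }
  out
}

node_best_split <- function(A, idx, gates, parent_crit, config, refine = TRUE) {
  n_node <- length(idx)
  best <- NULL
  gate_feats <- if (identical(config$gate_features, "all")) names(gates)
                else intersect(config$gate_features, names(gates))
  for (gf in gate_feats) {
    gx <- gates[[gf]][idx]
    ths <- gate_thresholds(gx, config$threshold_grid)
    sc <- score_thresholds(A, idx, gx, ths, parent_crit, n_node, config)
    if (is.null(sc)) next
    k <- which.max(sc$gain)
    if (is.null(best) || sc$gain[k] > best$gain + 1e-9) {
      best <- list(feature = gf, threshold = sc$threshold[k], gain = sc$gain[k],
                   n_left = sc$n_left[k], n_right = sc$n_right[k],
                   grid = ths)
    }
  }
  if (is.null(best) || best$gain <= 0) return(best)
  if (refine) {
    gx <- gates[[best$feature]][idx]
    j <- match(best$threshold, best$grid)
    lo <- if (j > 1L) best$grid[j - 1L] else -Inf
    hi <- if (j < length(best$grid)) best$grid[j + 1L] else Inf
    ux <- sort(unique(gx[gx > lo & gx < hi]))
    fine <- if (length(ux) >= 2L) (ux[-1] + ux[-length(ux)]) / 2 else numeric(0)
    fine <- setdiff(fine, best$threshold)
    if (length(fine) > 256L) {
      fine <- unique(stats::quantile(fine, probs = seq_len(256L) / 257, type = 1,
                                     names = FALSE))
    }
    if (length(fine)) {
      sc <- score_thresholds(A, idx, gx, sort(fine), parent_crit, n_node, config)
      if (!is.null(sc)) {
        k <- which.max(sc$gain)
        if (sc$gain[k] > best$gain) {
          best$threshold <- sc$threshold[k]
          best$gain <- sc$gain[k]
          best$n_left <- sc$n_left[k]; best$n_right <- sc$n_right[k]
        }
      }
    }
  }
  best$grid <- NULL
  best
}

# Fast-path best split of one node given as a transition table; used by the
# greedy recursion and, with refine = FALSE, comparable to
# brute_force_best_split on the same candidate grid.
find_best_split <- function(node_data, config = fit_config(), refine = FALSE) {
  xy <- extract_xy(node_data)
  A <- cbind(`(intercept)` = 1, xy$X, .y = xy$y)
  parent <- forward_select_sscp(crossprod(A), length(xy$y), config)
  best <- node_best_split(A, seq_len(nrow(A)), xy$gates, parent$criterion,
                          config, refine = refine)
  best %||% list(feature = NA_character_, threshold = NA_real_, gain = -Inf)
}

#' Score one candidate split
#'
#' Criterion gain of splitting a node at `feature >= threshold`: the sum of
#' the two children's penalised leaf-fit criteria minus the parent's. The
#' same criterion drives split acceptance in [fit_partition()]. Undersized
#' children make the candidate infeasible (`-Inf` gain), not an error.
#'
#' @param node_data Transition table rows at the node (see
#'   [encode_transitions()]).
#' @param feature Gate feature (`bmi_baseline`, `age_baseline`, `sex_male`).
#' @param threshold Numeric threshold; rows with `feature >= threshold` go
#'   right.
#' @param config A [fit_config()].
#' @return List with `gain`, `feasible`, child sizes and criteria.
#' @export
score_split <- function(node_data, feature, threshold, config = fit_config()) {
  xy <- extract_xy(node_data)
  gx <- xy$gates[[feature]]
  if (is.null(gx)) stop_domain("unknown gate feature: ", feature)
  right <- gx >= threshold
  nl <- sum(!right); nr <- sum(right)
  M <- sscp_of(xy$X, xy$y)
  parent <- forward_select_sscp(M, length(xy$y), config)
  if (nl < config$min_leaf_n || nr < config$min_leaf_n) {
    return(list(gain = -Inf, feasible = FALSE, n_left = nl, n_right = nr))
  }
  ML <- sscp_of(xy$X[!right, , drop = FALSE], xy$y[!right])
  fl <- forward_select_sscp(ML, nl, config)
  fr <- forward_select_sscp(M - ML, nr, config)
  list(gain = fl$criterion + fr$criterion - parent$criterion, feasible = TRUE,
       n_left = nl, n_right = nr,
       criterion_parent = parent$criterion,
       criterion_left = fl$criterion, criterion_right = fr$criterion)
}

#' Exhaustive split search (test oracle)
#'
#' Enumerates every candidate `(gate feature, grid threshold)` pair at a node
#' and fits both children by a naive `lm`-based forward selection, entirely
#' independent of the sweep-operator fast path used by [fit_partition()].
#' Intended as the greedy step's oracle on small instances.
#'
#' @param node_data Transition table rows (<= a few hundred for practicality).
#' @param config A [fit_config()].
#' @return List with the best `feature`, `threshold`, `gain`, or
#'   `list(feature = NA)` when no candidate is feasible ("no split").
#' @export
brute_force_best_split <- function(node_data, config = fit_config()) {
  xy <- extract_xy(node_data)
  n <- length(xy$y)
  parent <- fit_leaf_lm(xy$X, xy$y, config)
  best <- list(feature = NA_character_, threshold = NA_real_, gain = -Inf)
  gate_feats <- if (identical(config$gate_features, "all")) names(xy$gates)
                else intersect(config$gate_features, names(xy$gates))
  for (gf in gate_feats) {
    gx <- xy$gates[[gf]]
    for (t in gate_thresholds(gx, config$threshold_grid)) {
      right <- gx >= t
      nl <- sum(!right); nr <- sum(right)
      if (nl < config$min_leaf_n || nr < config$min_leaf_n) next
      fl <- fit_leaf_lm(xy$X[!right, , drop = FALSE], xy$y[!right], config)
      fr <- fit_leaf_lm(xy$X[right, , drop = FALSE], xy$y[right], config)
      gain <- fl$criterion + fr$criterion - parent$criterion
      if (gain > best$gain + 1e-9) {
        best <- list(feature = gf, threshold = t, gain = gain)
      }
    }
  }
  best
}

# Naive forward selection via repeated lm.fit calls (oracle path).
fit_leaf_lm <- function(X, y, config) {
  n <- length(y)
  pen <- penalty_per_param(n, config)
  sel <- integer(0)
  rss <- sum((y - mean(y))^2)
  rss <- max(rss, n * 1e-10)
  repeat {
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (!length(cand)) break
    rss_new <- vapply(cand, function(j) {
      Z <- cbind(1, X[, c(sel, j), drop = FALSE])
      f <- stats::lm.fit(Z, y)
      if (any(is.na(f$coefficients))) return(Inf)
      sum(f$residuals^2)
    }, numeric(1))
    rss_new <- pmax(rss_new, n * 1e-10)
    dcrit <- n / 2 * (log(rss) - log(rss_new)) - pen
    k <- which.max(dcrit)
    if (!is.finite(dcrit[k]) || dcrit[k] <= 0) break
    sel <- c(sel, cand[k])
    rss <- rss_new[k]
  }
  f <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  list(selected = sort(sel), rss = rss,
       criterion = leaf_criterion(rss, n, length(sel), config),
       bias = f$coefficients[1],
       coefs = stats::setNames(f$coefficients[-1], colnames(X)[sel]))
}

#' Fit a gating tree with sparse linear leaves
#'
#' Greedy top-down search: at each node every candidate gate split is scored
#' by the penalised-likelihood gain; the best candidate is accepted iff its
#' gain is positive and the depth budget allows, and the search recurses into
#' both children. Leaves are fitted by [fit_leaf_regression()]'s forward
#' selection. The fit is deterministic given the data and configuration.
#'
#' @param transitions Transition table from [encode_transitions()] (complete
#'   cases).
#' @param config A [fit_config()].
#' @return An `hml_fit`: `model` (a `pwl_model`), `trace` (one row per
#'   accepted split), `leaf_n`, and the `config`.
#' @export
fit_partition <- function(transitions, config = fit_config()) {
  if (!nrow(transitions)) stop_domain("empty training data")
  xy <- extract_xy(transitions)
  if (anyNA(xy$X) || anyNA(xy$y)) {
    stop_domain("training table must be complete-case")
  }
  A <- cbind(`(intercept)` = 1, xy$X, .y = xy$y)
  trace <- NULL
  next_id <- 0L
  leaves <- list()

  grow <- function(idx, depth) {
    M <- crossprod(A[idx, , drop = FALSE])
    fit <- forward_select_sscp(M, length(idx), config)
    cand <- if (depth < config$max_depth && length(idx) >= 2L * config$min_leaf_n) {
      node_best_split(A, idx, xy$gates, fit$criterion, config)
    } else NULL
    if (!is.null(cand) && cand$gain > 0) {
      right <- xy$gates[[cand$feature]][idx] >= cand$threshold
      trace <<- rbind(trace, data.frame(
        depth = depth, feature = cand$feature, threshold = cand$threshold,
        gain = cand$gain, n_left = cand$n_left, n_right = cand$n_right))
      left_node <- grow(idx[!right], depth + 1L)
      right_node <- grow(idx[right], depth + 1L)
      return(new_gate(cand$feature, cand$threshold, left_node, right_node))
    }
    next_id <<- next_id + 1L
    lf <- new_leaf_formula(next_id, fit$bias, fit$coefs, n = length(idx))
    attr(lf, "criterion") <- fit$criterion
    attr(lf, "rss") <- fit$rss
    leaves[[next_id]] <<- lf
    new_leaf_node(next_id)
  }

  tree <- grow(seq_len(nrow(A)), 0L)
  model <- pwl_model(tree, leaves,
                     meta = list(source = "hml_fit",
                                 n_train = nrow(A),
                                 split_penalty = config$split_penalty,
                                 seed = config$seed))
  structure(list(model = model, trace = trace,
                 leaf_n = vapply(leaves, function(l) l$n, integer(1)),
                 config = config),
            class = "hml_fit")
}

#' @export
print.hml_fit <- function(x, ...) {
  cat("Heterogeneous-mixture fit:", length(x$model$leaves), "leaves,",
      if (is.null(x$trace)) 0L else nrow(x$trace), "split(s)\n")
  print(x$model)
  invisible(x)
}
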