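# Feature selection: degenerate-column removal, pairwise-correlation
# pruning, CFS-merit subset search, remove-one backward elimination, and
# the n/4 feature budget. Every stage takes and returns a descriptor
# tibble; the audit trail accumulates in attr "selection_report".

report_rows <- function(stage, columns, reason, statistic = NA_real_) {
  tibble(stage = stage, column = columns, reason = reason,
         statistic = statistic)
}

append_report <- function(x, rows) {
  attr(x, "selection_report") <- bind_rows(selection_report(x), rows)
  x
}

#' Retrieve the accumulated selection report
#'
#' @param x A descriptor tibble that has passed through one or more
#'   selection stages.
#' @return Tibble with columns `stage`, `column`, `reason`, `statistic`
#'   — one row per removed column.
#' @export
selection_report <- function(x) {
  attr(x, "selection_report") %||%
    tibble(stage = character(), column = character(),
           reason = character(), statistic = numeric())
}

#' Remove degenerate descriptor columns
#'
#' Drops columns that are all-zero and columns with zero variance
#' (constant across compounds); such columns carry no information and
#' break correlation-based stages downstream.
#'
#' @param descriptors Descriptor tibble (`compound_id` + numeric
#'   columns).
#' @return Reduced descriptor tibble; removals recorded in the
#'   selection report (see [selection_report()]).
#' @export
drop_degenerate <- function(descriptors) {
  check_descriptor_tbl(descriptors)
  feats <- feature_names(descriptors)
  if (length(feats) == 0) abort("Descriptor table has no feature columns.")
  m <- feature_matrix(descriptors)
  all_zero <- feats[colSums(m != 0) == 0]
  zero_var <- setdiff(feats[apply(m, 2, sd) == 0], all_zero)
  removed <- c(all_zero, zero_var)
  if (length(removed) == length(feats)) {
    abort("no informative descriptors: every column is degenerate")
  }
  out <- descriptors |> select(-dplyr::all_of(removed))
  out <- append_report(out, bind_rows(
    report_rows("zero_value", all_zero, "all values zero", 0),
    report_rows("zero_value", zero_var, "zero variance", 0)))
  out
}

#' Prune highly correlated descriptor pairs
#'
#' Greedy scan over feature pairs with `|r|` above the cutoff (default
#' 0.9, the classical QSAR collinearity threshold): from each offending
#' pair the column less correlated with the activity is removed (ties
#' remove the lexicographically later name). The result contains no
#' pair above the cutoff.
#'
#' @param descriptors Descriptor tibble with no zero-variance columns
#'   (run [drop_degenerate()] first).
#' @param activity Numeric activity vector aligned to rows.
#' @param cutoff Absolute pairwise correlation threshold in (0, 1\].
#' @return Reduced descriptor tibble with report.
#' @export
prune_correlated <- function(descriptors, activity, cutoff = 0.9) {
  check_descriptor_tbl(descriptors)
  if (nrow(descriptors) < 3) abort("Need at least 3 compounds for correlation pruning.")
  if (length(activity) != nrow(descriptors)) abort("`activity` length mismatch.")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    abort("`cutoff` must lie in (0, 1].")
  }
  feats <- feature_names(descriptors)
  m <- feature_matrix(descriptors)
  if (any(apply(m, 2, sd) == 0)) {
    abort("Zero-variance column present; run drop_degenerate() first.")
  }
  cm <- abs(cor(m))
  diag(cm) <- 0
  r_act <- abs(cor(m, activity)[, 1])

  alive <- setNames(rep(TRUE, length(feats)), feats)
  removed <- character()
  stat <- numeric()
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx <= cutoff) break
    idx <- which(sub == mx, arr.ind = TRUE)[1, ]
    pair <- rownames(sub)[idx]
    victim <- if (r_act[pair[1]] < r_act[pair[2]]) pair[1]
              else if (r_act[pair[2]] < r_act[pair[1]]) pair[2]
              else sort(pair)[2]
    alive[victim] <- FALSE
    removed <- c(removed, victim)
    stat <- c(stat, mx)
  }
  out <- descriptors |> select(-dplyr::all_of(removed))
  append_report(out, report_rows(
    "correlation_prune", removed,
    sprintf("|r| > %.3g with retained descriptor", cutoff), stat))
}

# CFS merit of a feature subset given precomputed |correlation|
# structures: k * mean|r_cf| / sqrt(k + k(k-1) * mean|r_ff|).
cfs_merit_idx <- function(idx, acf, aff) {
  k <- length(idx)
  rcf <- mean(acf[idx])
  if (k == 1) return(rcf)
  rff <- (sum(aff[idx, idx]) - k) / (k * (k - 1))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature subset selection (CFS)
#'
#' Scores subsets by the CFS merit
#' `k * rcf / sqrt(k + k(k-1) * rff)`, where `rcf` is the mean absolute
#' feature-activity correlation and `rff` the mean absolute
#' feature-feature correlation — favouring features correlated with the
#' activity but not with each other. Search is exhaustive for up to 15
#' features and best-first (with a bounded expansion budget and
#' early stop after non-improving expansions) above that.
#'
#' @param descriptors Descriptor tibble, already pruned.
#' @param activity Activity vector aligned to rows.
#' @param max_subset Maximum subset size returned.
#' @param max_expansions Best-first node-expansion budget.
#' @param patience Stop after this many consecutive expansions that do
#'   not improve the best merit.
#' @return Descriptor tibble reduced to the best subset, with attributes
#'   `"merit"` (its CFS merit) and the accumulated report.
#' @export
cfs_select <- function(descriptors, activity, max_subset = NULL,
                       max_expansions = 200, patience = 5) {
  check_descriptor_tbl(descriptors)
  feats <- feature_names(descriptors)
  if (length(feats) == 0) abort("Empty descriptor table.")
  if (is.null(max_subset)) max_subset <- length(feats)
  if (max_subset < 1) abort("`max_subset` must be at least 1.")
  m <- feature_matrix(descriptors)
  acf <- abs(cor(m, activity)[, 1])
  aff <- abs(cor(m))
  p <- length(feats)

  if (p <= 15) {
    best <- cfs_exhaustive(acf, aff, max_subset)
  } else {
    best <- cfs_best_first(acf, aff, max_subset, max_expansions, patience)
  }
  keep <- sort(feats[best$idx])
  removed <- setdiff(feats, keep)
  out <- descriptors |>
    select("compound_id", dplyr::all_of(keep))
  attr(out, "selection_report") <- selection_report(descriptors)
  out <- append_report(out, report_rows(
    "cfs", removed, "not in best-merit subset", NA_real_))
  attr(out, "merit") <- best$merit
  out
}

cfs_exhaustive <- function(acf, aff, max_subset) {
  p <- length(acf)
  best_idx <- NULL
  best_merit <- -Inf
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) > max_subset) next
    merit <- cfs_merit_idx(idx, acf, aff)
    if (merit > best_merit + 1e-12) {
      best_merit <- merit
      best_idx <- idx
    }
  }
  list(idx = best_idx, merit = best_merit)
}

cfs_best_first <- function(acf, aff, max_subset, max_expansions, patience) {
  p <- length(acf)
  key <- function(idx) paste(idx, collapse = ",")
  # frontier: list of list(idx, merit); start from the single best feature
  start <- which.max(acf)
  frontier <- list(list(idx = start, merit = acf[[start]]))
  visited <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = visited)
  best <- frontier[[1]]
  stale <- 0L
  expansions <- 0L
  while (length(frontier) > 0 && expansions < max_expansions && stale < patience) {
    merits <- map_dbl(frontier, "merit")
    pick <- which.max(merits)
    node <- frontier[[pick]]
    frontier <- frontier[-pick]
    expansions <- expansions + 1L
    improved <- FALSE
    if (length(node$idx) < max_subset) {
      for (f in setdiff(seq_len(p), node$idx)) {
        idx <- sort(c(node$idx, f))
        k <- key(idx)
        if (exists(k, envir = visited, inherits = FALSE)) next
        assign(k, TRUE, envir = visited)
        merit <- cfs_merit_idx(idx, acf, aff)
        frontier <- c(frontier, list(list(idx = idx, merit = merit)))
        if (merit > best$merit + 1e-12) {
          best <- list(idx = idx, merit = merit)
          improved <- TRUE
        }
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(idx = best$idx, merit = best$merit)
}

#' Remove-one backward elimination under cross-validated correlation
#'
#' Backward elimination driven by the model-evaluation statistic itself:
#' in each cycle the current feature set is scored by k-fold
#' cross-validated Pearson R of an epsilon-SVR, then every
#' leave-one-descriptor-out subset is scored; the descriptor whose
#' removal yields the largest R that is at least the current R is
#' permanently removed. The loop stops when every removal would decrease
#' R, so the cross-validated R trajectory is non-decreasing.
#'
#' @param descriptors Descriptor tibble (at least 2 features).
#' @param activity Activity vector.
#' @param config An [svr_config()] defining the SVR and the CV protocol;
#'   its seed fixes fold assignment for every scoring call.
#' @return Reduced descriptor tibble with attributes `"trajectory"`
#'   (the cycle-by-cycle CV R values) and the accumulated report.
#' @export
f_stepping <- function(descriptors, activity, config = svr_config()) {
  check_descriptor_tbl(descriptors)
  if (!all(is.finite(activity))) abort("Non-finite activity values.")
  feats <- feature_names(descriptors)
  if (length(feats) < 2) abort("Need at least 2 features for backward elimination.")
  folds <- make_folds(nrow(descriptors), config$cv_folds,
                      derive_seed(config$seed, "f_stepping"))
  m <- feature_matrix(descriptors)

  score <- function(cols) {
    cv_pearson(m[, cols, drop = FALSE], activity, folds, config)
  }

  current <- feats
  r_cur <- score(current)
  trajectory <- r_cur
  removed <- character()
  stat <- numeric()
  while (length(current) > 1) {
    cand <- map_dbl(current, function(f) score(setdiff(current, f)))
    names(cand) <- current
    best <- max(cand)
    if (best < r_cur) break
    # ties: remove the lexicographically later name for determinism
    victim <- sort(names(cand)[cand == best], decreasing = TRUE)[1]
    current <- setdiff(current, victim)
    removed <- c(removed, victim)
    stat <- c(stat, best)
    r_cur <- best
    trajectory <- c(trajectory, r_cur)
  }
  out <- descriptors |> select("compound_id", dplyr::all_of(current))
  attr(out, "selection_report") <- selection_report(descriptors)
  out <- append_report(out, report_rows(
    "f_stepping", removed, "removal did not decrease CV R", stat))
  attr(out, "trajectory") <- trajectory
  out
}

# Pooled out-of-fold Pearson R of an SVR over a fixed fold assignment.
cv_pearson <- function(x, y, folds, config) {
  preds <- rep(NA_real_, length(y))
  for (k in sort(unique(folds))) {
    hold <- folds == k
    fit <- fit_raw_svr(x[!hold, , drop = FALSE], y[!hold], config)
    preds[hold] <- predict_raw_svr(fit, x[hold, , drop = FALSE])
  }
  if (sd(preds) == 0 || sd(y) == 0) return(0)
  cor(y, preds)
}

#' Cap a feature set at the n/4 over-fitting budget
#'
#' Restricting the number of descriptors to less than one fourth of the
#' number of compounds guards against over-optimisation. If the set
#' exceeds the budget, the `floor(n_compounds/4)` features with the
#' largest absolute correlation to the activity are kept (ties broken
#' lexicographically).
#'
#' @param descriptors Descriptor tibble.
#' @param activity Activity vector.
#' @param n_compounds Number of compounds defining the budget; defaults
#'   to `nrow(descriptors)`.
#' @return Descriptor tibble with at most `floor(n_compounds/4)`
#'   features.
#' @export
enforce_budget <- function(descriptors, activity,
                           n_compounds = nrow(descriptors)) {
  check_descriptor_tbl(descriptors)
  if (n_compounds < 4) abort("Need at least 4 compounds for a feature budget.")
  feats <- feature_names(descriptors)
  budget <- floor(n_compounds / 4)
  if (length(feats) < n_compounds / 4) return(descriptors)
  r_act <- abs(cor(feature_matrix(descriptors), activity)[, 1])
  ord <- order(-r_act, names(r_act))
  keep <- names(r_act)[ord][seq_len(min(budget, length(feats)))]
  removed <- setdiff(feats, keep)
  out <- descriptors |> select("compound_id", dplyr::all_of(sort(keep)))
  attr(out, "selection_report") <- selection_report(descriptors)
  append_report(out, report_rows(
    "budget", removed,
    sprintf("feature budget floor(n/4) = %d", budget),
    unname(r_act[removed])))
}

#' Run the full three-stage feature selection pipeline
#'
#' Chains [drop_degenerate()], [prune_correlated()], [cfs_select()]
#' (capped at the n/4 budget), [f_stepping()] and [enforce_budget()].
#' The result is a pure function of (descriptors, activity, config).
#'
#' @inheritParams prune_correlated
#' @param config [svr_config()] used inside backward elimination.
#' @param budget Feature budget; default `floor(n/4)`.
#' @return Selected descriptor tibble with the full selection report.
#' @export
select_features <- function(descriptors, activity, cutoff = 0.9,
                            config = svr_config(),
                            budget = floor(nrow(descriptors) / 4)) {
  out <- descriptors |>
    drop_degenerate() |>
    prune_correlated(activity, cutoff = cutoff) |>
    cfs_select(activity, max_subset = budget)
  if (length(feature_names(out)) >= 2) {
    out <- f_stepping(out, activity, config = config)
  }
  enforce_budget(out, activity, n_compounds = nrow(descriptors))
}
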