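#' Row-index splits from a split plan
#'
#' Converts the id lists of a [make_split_plan()] result into row indices of
#' a feature matrix aligned with the cohort.
#'
#' @param plan a `split_plan`.
#' @param ids the cohort's id column (row-aligned with the features).
#' @param reps_use how many repetitions to keep (default: all).
#' @return list of `list(train, validation)` integer index pairs, plus
#'   attributes `test` and `pool` with the test / full-training-pool indices.
#' @export
plan_indices <- function(plan, ids, reps_use = length(plan$repetitions)) {
  reps_use <- min(reps_use, length(plan$repetitions))
  out <- lapply(plan$repetitions[seq_len(reps_use)], function(r) {
    list(train = match(r$train_ids, ids),
         validation = match(r$validation_ids, ids))
  })
  attr(out, "test") <- match(plan$test_ids, ids)
  attr(out, "pool") <- match(plan$threshold_pool_ids, ids)
  out
}

# Mean validation AUC of a feature set across repetitions: train on each
# repetition's undersampled training fold, score its naturally prevalent
# validation fold.
mean_validation_auc <- function(spec, features, labels, splits) {
  scores <- vapply(splits, function(sp) {
    m <- train_model(spec, features[sp$train, , drop = FALSE],
                     labels[sp$train])
    auc(predict_prob(m, features[sp$validation, , drop = FALSE]),
        labels[sp$validation])
  }, numeric(1))
  mean(scores)
}

#' Recursive feature elimination
#'
#' Starting from all columns, repeatedly retrains, scores the current set by
#' mean validation AUC across the repetitions, and drops the least important
#' feature (importance ranked on the first repetition's training fold).
#' Returns the best-scoring visited set of size at most `max_k`.
#'
#' @param spec a [model_spec()].
#' @param features feature data frame.
#' @param labels binary labels (row-aligned).
#' @param splits repetition index pairs from [plan_indices()].
#' @param max_k size cap of the returned set (default 10).
#' @return list with `features` (selected names), `score` (mean validation
#'   AUC) and `path` (data frame of visited sizes and scores).
#' @export
rfe_select <- function(spec, features, labels, splits, max_k = 10) {
  current <- colnames(features)
  if (length(current) == 0) stop("rfe_select needs at least one feature")
  path <- list()
  visited <- list()
  while (length(current) >= 1) {
    sub <- features[, current, drop = FALSE]
    score <- mean_validation_auc(spec, sub, labels, splits)
    path[[length(path) + 1]] <- data.frame(size = length(current),
                                           score = score)
    visited[[length(visited) + 1]] <- list(features = current, score = score)
    if (length(current) == 1) break
    tr <- splits[[1]]$train
    rk <- rank_importance(spec, sub[tr, , drop = FALSE], labels[tr])
    current <- setdiff(current, rk$feature[nrow(rk)])
  }
  ok <- Filter(function(v) length(v$features) <= max_k, visited)
  scores <- vapply(ok, function(v) v$score, numeric(1))
  sizes <- vapply(ok, function(v) length(v$features), numeric(1))
  best <- order(-scores, sizes)[1]
  list(features = ok[[best]]$features, score = ok[[best]]$score,
       path = do.call(rbind, path))
}

#' Ranked-prefix subset search
#'
#' Ranks the (at most 10) candidate features on the first repetition's
#' training fold and evaluates the k ranked-prefix sets {top-1} ... {top-k}
#' by mean validation AUC, returning the best (smallest set wins ties). An
#' exhaustive search over all non-empty subsets is available via
#' `exhaustive = TRUE`.
#'
#' @inheritParams rfe_select
#' @param exhaustive evaluate all `2^k - 1` subsets instead of the k
#'   prefixes.
#' @return list with `features`, `score` and `candidates` (per-set scores).
#' @export
best_subset <- function(spec, features, labels, splits, exhaustive = FALSE) {
  k <- ncol(features)
  if (k == 0) stop("best_subset needs at least one feature")
  if (k > 10) stop("best_subset expects at most 10 candidate features")
  tr <- splits[[1]]$train
  rk <- rank_importance(spec, features[tr, , drop = FALSE], labels[tr])
  sets <- if (exhaustive) {
    unlist(lapply(seq_len(k), function(m) {
      utils::combn(colnames(features), m, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    lapply(seq_len(k), function(m) rk$feature[seq_len(m)])
  }
  scores <- vapply(sets, function(s) {
    mean_validation_auc(spec, features[, s, drop = FALSE], labels, splits)
  }, numeric(1))
  sizes <- lengths(sets)
  best <- order(-scores, sizes)[1]
  cand <- data.frame(set = vapply(sets, paste, character(1), collapse = "+"),
                     size = sizes, score = scores)
  list(features = sets[[best]], score = scores[best], candidates = cand)
}

# One selection round: importance top-m filter, then RFE, then ranked-prefix
# subset search.
selection_round <- function(spec, features, labels, splits, pool,
                            top_m = 30, max_k = 10) {
  pool <- intersect(pool, colnames(features))
  sub <- features[, pool, drop = FALSE]
  tr <- splits[[1]]$train
  rk <- rank_importance(spec, sub[tr, , drop = FALSE], labels[tr])
  kept <- rk$feature[seq_len(min(top_m, nrow(rk)))]
  rfe <- rfe_select(spec, features[, kept, drop = FALSE], labels, splits,
                    max_k = max_k)
  bs <- best_subset(spec, features[, rfe$features, drop = FALSE], labels,
                    splits)
  list(pool = pool, importance = rk, rfe = rfe, subset = bs,
       selected = bs$features, score = bs$score)
}

#' Three-round feature selection
#'
#' Round 1 screens the anthropometric and the survey-based families
#' separately; Round 2 screens the union of the Round-1 survivors; Round 3
#' screens the Round-2 survivors together with the proposed criterion-scaled
#' synthetic features. Every round applies an importance top-`top_m` filter,
#' recursive feature elimination, and the ranked-prefix subset search, all
#' scored by mean validation AUC. Empty families are skipped with a warning.
#'
#' @param families named list with `anthropometric`, `survey`, `proposed`
#'   character vectors (see [feature_families()]).
#' @inheritParams rfe_select
#' @param top_m importance filter size (default 30).
#' @return a `selection_trace` list with the per-round results and the final
#'   feature set (size at most `max_k`).
#' @export
run_three_rounds <- function(families, spec, features, labels, splits,
                             top_m = 30, max_k = 10) {
  run_fam <- function(pool, label) {
    pool <- intersect(pool, colnames(features))
    if (length(pool) == 0) {
      warning(sprintf("feature family '%s' is empty; skipped", label))
      return(NULL)
    }
    selection_round(spec, features, labels, splits, pool, top_m, max_k)
  }
  r1a <- run_fam(families$anthropometric, "anthropometric")
  r1b <- run_fam(families$survey, "survey")
  pool2 <- unique(c(r1a$selected, r1b$selected))
  r2 <- if (length(pool2) > 0) {
    selection_round(spec, features, labels, splits, pool2, top_m, max_k)
  } else NULL
  pool3 <- unique(c(r2$selected,
                    intersect(families$proposed, colnames(features))))
  if (length(pool3) == 0) stop("no features available for the final round")
  r3 <- selection_round(spec, features, labels, splits, pool3, top_m, max_k)
  structure(list(round1_anthropometric = r1a, round1_survey = r1b,
                 round2 = r2, round3 = r3,
                 final_features = r3$selected, final_score = r3$score),
            class = "selection_trace")
}

#' Reduced hyperparameter grids
#'
#' Compact presets of the per-classifier tuning grids for desk-scale runs.
#'
#' @param algorithm algorithm name as in [model_spec()].
#' @return list of hyperparameter combinations.
#' @export
desk_grid <- function(algorithm) {
  switch(algorithm,
    logistic = list(list(standardize = TRUE)),
    cart_tree = {
      g <- expand.grid(criterion = c("gini", "entropy"),
                       max_depth = c(2, 3, 4, 5),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i) {
        list(criterion = g$criterion[i], max_depth = g$max_depth[i])
      })
    },
    random_forest = list(list(num_trees = 300, min_node_size = 4),
                         list(num_trees = 300, min_node_size = 10)),
    gradient_boosted_trees = list(
      list(nrounds = 150, max_depth = 4, eta = 0.05),
      list(nrounds = 150, max_depth = 4, eta = 0.1)),
    stop(sprintf("no grid preset for algorithm '%s'", algorithm))
  )
}

#' Exhaustive grid search by mean validation AUC
#'
#' @param algorithm algorithm name.
#' @param grid non-empty list of hyperparameter lists.
#' @inheritParams rfe_select
#' @param seed seed passed to each [model_spec()].
#' @return list with `best` (hyperparameter list), `best_score` and `scores`
#'   per grid point; ties resolve to the first grid entry.
#' @export
tune_grid <- function(algorithm, grid, features, labels, splits, seed = 1L) {
  if (length(grid) == 0) stop("tune_grid: empty grid")
  scores <- vapply(grid, function(hp) {
    mean_validation_auc(model_spec(algorithm, hp, seed = seed),
                        features, labels, splits)
  }, numeric(1))
  best <- which.max(scores) # which.max takes the first maximum
  list(best = grid[[best]], best_score = scores[best], scores = scores)
}
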