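#' Undersample to a 1:1 class ratio
#'
#' Keeps every positive and samples negatives without replacement down to the
#' positive count. Raises an error if either class is absent. When there are
#' fewer negatives than positives the set is returned unchanged (already at or
#' below 1:1).
#'
#' @param ids identifier vector.
#' @param labels 0/1 (or logical) labels aligned with `ids`.
#' @param seed integer seed for the negative subsample.
#' @return subset of `ids` with balanced classes.
#' @export
undersample <- function(ids, labels, seed) {
  labels <- as.logical(labels)
  pos <- ids[labels]
  neg <- ids[!labels]
  if (length(pos) == 0) stop("undersample: no positive records")
  if (length(neg) == 0) stop("undersample: no negative records")
  set.seed(as.integer(seed))
  if (length(neg) > length(pos)) {
    neg <- sample(neg, length(pos))
  }
  c(pos, neg)
}

#' Repeated-split protocol
#'
#' One stratified 9:1 test split, then `reps` repeated 9:1 train/validation
#' splits of the remaining pool. The training portion of each repetition is
#' undersampled to a 1:1 MetS ratio (fresh undersample per repetition);
#' validation sets keep their natural prevalence. Repetition seeds are derived
#' deterministically from the master seed.
#'
#' @param records labeled cohort (needs `id` and `mets` columns; run
#'   [label_cohort()] first if absent).
#' @param test_frac fraction held out once for testing (default 0.1).
#' @param val_frac fraction of the training pool re-split per repetition
#'   (default 0.1).
#' @param reps number of repetitions (default 30).
#' @param seed master seed.
#' @return a `split_plan`: list with `test_ids`, `threshold_pool_ids` (the
#'   full pre-undersampling training pool) and `repetitions`, each holding
#'   `train_ids` (undersampled), `validation_ids` and the repetition seed.
#' @export
make_split_plan <- function(records, test_frac = 0.1, val_frac = 0.1,
                            reps = 30, seed = 1L) {
  if (!"mets" %in% names(records)) {
    stop("records must carry a 'mets' column; run label_cohort() first")
  }
  y <- as.logical(records$mets)
  if (!any(y) || all(y)) {
    stop("split plan needs both classes present in the cohort")
  }
  ids <- records$id
  set.seed(as.integer(seed))
  # sizes by ceiling (9:1 of 63,333 gives a 6,334-record validation set);
  # test split stratified by label for variance control
  n_test <- ceiling(length(ids) * test_frac)
  pos_ids <- ids[y]
  neg_ids <- ids[!y]
  n_test_pos <- round(length(pos_ids) * test_frac)
  test_ids <- c(sample(pos_ids, n_test_pos),
                sample(neg_ids, n_test - n_test_pos))
  pool <- setdiff(ids, test_ids)
  pool_y <- y[match(pool, ids)]
  n_val <- ceiling(length(pool) * val_frac)
  repetitions <- vector("list", reps)
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, r)
    set.seed(rs)
    val_ids <- sample(pool, n_val)
    tr_ids <- setdiff(pool, val_ids)
    tr_y <- pool_y[match(tr_ids, pool)]
    tr_us <- undersample(tr_ids, tr_y, seed = derive_seed(rs, 104729L))
    repetitions[[r]] <- list(train_ids = tr_us, validation_ids = val_ids,
                             seed = rs)
  }
  structure(list(test_ids = test_ids, threshold_pool_ids = pool,
                 repetitions = repetitions, seed = as.integer(seed)),
            class = "split_plan")
}

#' Serialise / restore a split plan as JSON
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reps <- x$repetitions
  if (is.data.frame(reps)) {
    reps <- lapply(seq_len(nrow(reps)), function(i) {
      list(train_ids = reps$train_ids[[i]],
           validation_ids = reps$validation_ids[[i]],
           seed = reps$seed[[i]])
    })
  }
  structure(list(test_ids = x$test_ids,
                 threshold_pool_ids = x$threshold_pool_ids,
                 repetitions = reps, seed = x$seed),
            class = "split_plan")
}
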