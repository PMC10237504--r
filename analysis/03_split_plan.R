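#!/usr/bin/env Rscript
# The repeated-split protocol: one stratified 9:1 test split, thirty 9:1
# train/validation re-splits, training folds undersampled to a 1:1 MetS
# ratio, validation and test kept at natural prevalence.
source(file.path("analysis", "00_common.R"))

cohort <- study_cohort()
plan <- study_plan(cohort)

train_sizes <- vapply(plan$repetitions, function(r) length(r$train_ids),
                      numeric(1))
val_prev <- vapply(plan$repetitions, function(r) {
  mean(cohort$mets[match(r$validation_ids, cohort$id)])
}, numeric(1))
test_prev <- mean(cohort$mets[match(plan$test_ids, cohort$id)])

tab <- data.frame(
  sample = c("all", "training (undersampled)", "validation", "test"),
  number = c(1, 30, 30, 1),
  size = c(nrow(cohort), sprintf("%.0f +/- %.0f", mean(train_sizes),
                                 sd(train_sizes)),
           length(plan$repetitions[[1]]$validation_ids),
           length(plan$test_ids)),
  mets_pct = c(100 * prevalence(cohort), 50.0,
               sprintf("%.1f +/- %.1f", 100 * mean(val_prev),
                       100 * sd(val_prev)),
               round(100 * test_prev, 1))
)
write.csv(tab, file.path(RESULTS_DIR, "split_summary.csv"), row.names = FALSE)
message(sprintf(
  "splits: test %d (%.1f%% MetS); 30 training folds of %.0f +/- %.0f at 50%%; validation %.1f +/- %.1f%%",
  length(plan$test_ids), 100 * test_prev, mean(train_sizes), sd(train_sizes),
  100 * mean(val_prev), 100 * sd(val_prev)))
message("wrote results/split_summary.csv")
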