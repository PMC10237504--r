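#!/usr/bin/env Rscript
# Hyperparameter tuning on the reduced grids, scored by mean validation AUC
# over the first five repetitions, for the features selected in step 04.
source(file.path("analysis", "00_common.R"))

sel <- read.csv(file.path(RESULTS_DIR, "selected_features.csv"))
cohort <- study_cohort()
plan <- study_plan(cohort)
idx <- plan_indices(plan, cohort$id, reps_use = 5)

rows <- list()
for (algo in unique(sel$algorithm)) {
  feats_n <- sel$feature[sel$algorithm == algo]
  feats <- build_feature_matrix(cohort, feats_n)
  grid <- desk_grid(algo)
  tuned <- tune_grid(algo, grid, feats, cohort$mets, idx,
                     seed = MASTER_SEED)
  # untuned baseline: the family's default hyperparameters
  base_auc <- mean(vapply(idx, function(sp) {
    m <- train_model(model_spec(algo, seed = MASTER_SEED),
                     feats[sp$train, , drop = FALSE],
                     cohort$mets[sp$train])
    auc(predict_prob(m, feats[sp$validation, , drop = FALSE]),
        cohort$mets[sp$validation])
  }, numeric(1)))
  message(sprintf("%s: val AUC %.3f untuned -> %.3f tuned (%s)",
                  algo, base_auc, tuned$best_score,
                  paste(names(tuned$best), unlist(tuned$best),
                        sep = "=", collapse = ", ")))
  rows[[algo]] <- data.frame(
    algorithm = algo,
    best_params = paste(names(tuned$best), unlist(tuned$best), sep = "=",
                        collapse = "; "),
    untuned_val_auc = base_auc, tuned_val_auc = tuned$best_score)
}
write.csv(do.call(rbind, rows), file.path(RESULTS_DIR, "tuning.csv"),
          row.names = FALSE)
message("wrote results/tuning.csv")
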