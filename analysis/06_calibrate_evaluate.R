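#!/usr/bin/env Rscript
# Calibration comparison and held-out evaluation. For each family: fit the
# tuned model on the first repetition's undersampled training fold, compare
# calibration methods (fitted on that repetition's validation fold), and
# evaluate the best-calibrated probabilities on the untouched test split at
# the undersampling-corrected decision threshold.
source(file.path("analysis", "00_common.R"))

sel <- read.csv(file.path(RESULTS_DIR, "selected_features.csv"))
tun <- read.csv(file.path(RESULTS_DIR, "tuning.csv"))
cohort <- study_cohort()
plan <- study_plan(cohort)
idx <- plan_indices(plan, cohort$id)
test_i <- attr(idx, "test")
pool_i <- attr(idx, "pool")
threshold <- pozzolo_threshold(cohort$mets[pool_i])
message(sprintf("corrected decision threshold: %.3f (training-pool prevalence)",
                threshold))

parse_params <- function(s) {
  if (!nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, "; ")[[1]], "=")
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

cal_rows <- list()
met_rows <- list()
for (algo in unique(sel$algorithm)) {
  feats_n <- sel$feature[sel$algorithm == algo]
  feats <- build_feature_matrix(cohort, feats_n)
  hp <- parse_params(tun$best_params[tun$algorithm == algo])
  spec <- model_spec(algo, hp, seed = MASTER_SEED)
  rep1 <- idx[[1]]
  model <- train_model(spec, feats[rep1$train, , drop = FALSE],
                       cohort$mets[rep1$train])
  tr_pool <- setdiff(pool_i, rep1$validation)
  beta <- sum(cohort$mets[tr_pool] == 1) / sum(cohort$mets[tr_pool] == 0)
  calsel <- select_calibration(model,
                               feats[rep1$validation, , drop = FALSE],
                               cohort$mets[rep1$validation],
                               feats[test_i, , drop = FALSE],
                               cohort$mets[test_i], beta = beta,
                               methods = c("none", "platt", "isotonic",
                                           "pozzolo"))
  for (r in calsel$reports) {
    cal_rows[[paste(algo, r$method)]] <- data.frame(
      algorithm = algo, method = r$method, brier = r$brier,
      spiegelhalter_z = r$spiegelhalter_z,
      spiegelhalter_p = r$spiegelhalter_p,
      selected = r$method == calsel$best)
  }
  p_test <- calsel$calibrators[[calsel$best]](
    predict_prob(model, feats[test_i, , drop = FALSE]))
  pan <- metric_panel(p_test, cohort$mets[test_i], threshold)
  message(sprintf(
    "%s (+%s): test AUC %.3f, recall %.3f, specificity %.3f, BACC %.3f",
    algo, calsel$best, pan$auc, pan$recall, pan$specificity, pan$bacc))
  met_rows[[algo]] <- data.frame(
    algorithm = algo, calibration = calsel$best,
    auc = pan$auc, recall = pan$recall, specificity = pan$specificity,
    bacc = pan$bacc, ppv = pan$ppv, npv = pan$npv,
    n_features = length(feats_n),
    n_raw_features = raw_feature_count(feats_n), threshold = threshold,
    beta = beta)
}
write.csv(do.call(rbind, cal_rows),
          file.path(RESULTS_DIR, "calibration.csv"), row.names = FALSE)
write.csv(do.call(rbind, met_rows),
          file.path(RESULTS_DIR, "model_report.csv"), row.names = FALSE)
message("wrote results/calibration.csv and results/model_report.csv")
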