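#!/usr/bin/env Rscript
# The MetS risk map: refit the tuned CART on the plane-expressible subset of
# its selected features, convert the terminal nodes into regions of the
# (WC, BP) unit square, attach undersampling-corrected risk ratios, and
# export the map with raw-value axis tables.
source(file.path("analysis", "00_common.R"))

sel <- read.csv(file.path(RESULTS_DIR, "selected_features.csv"))
cohort <- study_cohort()
plan <- study_plan(cohort)
idx <- plan_indices(plan, cohort$id)
pool_i <- attr(idx, "pool")
rep1 <- idx[[1]]

map_feats <- intersect(sel$feature[sel$algorithm == "cart_tree"],
                       mappable_features())
if (length(map_feats) == 0) map_feats <- c("BPWC_add", "BPWC_mul", "BPWC_dif")
feats <- build_feature_matrix(cohort, map_feats)
model <- train_model(model_spec("cart_tree", seed = MASTER_SEED),
                     feats[rep1$train, , drop = FALSE],
                     cohort$mets[rep1$train])
tr_pool <- setdiff(pool_i, rep1$validation)
beta <- sum(cohort$mets[tr_pool] == 1) / sum(cohort$mets[tr_pool] == 0)
threshold <- pozzolo_threshold(cohort$mets[pool_i])
map <- build_risk_map(model, threshold, beta = beta)

message(sprintf("risk map over {%s}: %d regions, threshold %.3f",
                paste(map_feats, collapse = ", "), length(map$regions),
                threshold))
regions <- do.call(rbind, lapply(map$regions, function(r) {
  data.frame(leaf = r$leaf,
             rules = paste(vapply(r$constraints, function(cn) {
               sprintf("%s %s %.3f", cn$var, cn$op, cn$threshold)
             }, character(1)), collapse = " & "),
             calibrated_prob = r$calibrated_prob, risk = r$risk,
             class = ifelse(r$class, "MetS", "non-MetS"), zone = r$zone,
             ppv_zone = r$ppv_zone)
}))
write.csv(regions, file.path(RESULTS_DIR, "risk_map_regions.csv"),
          row.names = FALSE)
export_map(map, file.path(RESULTS_DIR, "risk_map.json"))

# the worked example participant lands here:
wc <- scaled_wc(89, "F")
bp <- scaled_bp(140, 90)
reg <- locate(map, wc, bp)
message(sprintf(
  "worked example (WC %.2f, BP %.2f): %s, risk %.2f x prevalence, %s zone",
  wc, bp, ifelse(reg$class, "MetS", "non-MetS"), reg$risk, reg$zone))

ticks <- do.call(rbind, lapply(c("WC-male", "WC-female", "BP-systolic",
                                 "BP-diastolic"), function(ax) {
  cbind(axis = ax, raw_axis_ticks(ax, seq(0.1, 0.9, 0.1)))
}))
write.csv(ticks, file.path(RESULTS_DIR, "risk_map_axis_ticks.csv"),
          row.names = FALSE)
message("wrote results/risk_map_regions.csv, results/risk_map.json and results/risk_map_axis_ticks.csv")
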