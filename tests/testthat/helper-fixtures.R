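# Shared fixtures, built in code.

# One participant row with sensible defaults, overridable per field.
make_record <- function(sex = "M", age = 50, height = 170, weight = 70,
                        waist = 80, hip = 95, sbp = 115, dbp = 70,
                        glucose = 90, triglycerides = 100, hdl = 60,
                        id = "P000001") {
  data.frame(id = id, sex = sex, age = age, height = height, weight = weight,
             waist = waist, hip = hip, sbp = sbp, dbp = dbp,
             glucose = glucose, triglycerides = triglycerides, hdl = hdl,
             stringsAsFactors = FALSE)
}

# A record whose five risk-factor states are set by flag: values comfortably
# past (or short of) each cutoff for a male participant.
record_with_flags <- function(waist_f, bp_f, glu_f, tg_f, hdl_f) {
  make_record(sex = "M",
              waist = if (waist_f) 95 else 80,
              sbp = if (bp_f) 140 else 115, dbp = if (bp_f) 90 else 70,
              glucose = if (glu_f) 110 else 90,
              triglycerides = if (tg_f) 200 else 100,
              hdl = if (hdl_f) 35 else 60)
}

# Small labeled synthetic cohort, memoised per (n, seed).
local({
  cache <- new.env(parent = emptyenv())
  small_cohort <<- function(n = 2000, seed = 42) {
    key <- paste(n, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- label_cohort(generate_cohort(cohort_spec(n, seed = seed)))
    }
    cache[[key]]
  }
})

# Fit a small CART on the three BPWC combination features of a cohort.
fit_bpwc_tree <- function(cohort, plan = NULL, seed = 42, max_depth = 5) {
  feats <- build_feature_matrix(cohort, c("BPWC_add", "BPWC_mul", "BPWC_dif"))
  if (is.null(plan)) plan <- make_split_plan(cohort, reps = 1, seed = seed)
  idx <- plan_indices(plan, cohort$id)
  model <- train_model(model_spec("cart_tree",
                                  list(max_depth = max_depth), seed = seed),
                       feats[idx[[1]]$train, ], cohort$mets[idx[[1]]$train])
  list(model = model, features = feats, idx = idx, plan = plan)
}
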