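# Shared settings for the numbered analysis scripts. Each script is
# self-contained: it regenerates the (deterministic) cohort and split plan
# from MASTER_SEED instead of passing multi-megabyte intermediates around.
suppressPackageStartupMessages(library(metsrisk))

MASTER_SEED <- 2026L
COHORT_N <- 20000L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_cohort <- function() {
  label_cohort(generate_cohort(cohort_spec(COHORT_N, seed = MASTER_SEED)))
}

study_plan <- function(cohort) {
  make_split_plan(cohort, reps = 30, seed = MASTER_SEED)
}
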