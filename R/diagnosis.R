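#' Diagnostic criteria for metabolic syndrome
#'
#' Cutoffs of the revised NCEP ATP III definition with the Korean Society for
#' Obesity waist-circumference criteria. A participant is diagnosed with MetS
#' when at least three of the five risk factors are present:
#' abdominal obesity (waist >= 90 cm male / >= 85 cm female), elevated blood
#' pressure (sbp >= 130 or dbp >= 85 mmHg), elevated fasting glucose
#' (>= 100 mg/dl), elevated triglycerides (>= 150 mg/dl), and reduced HDL
#' cholesterol (<= 40 mg/dl male / <= 50 mg/dl female).
#'
#' @param waist_male,waist_female waist cutoffs in cm.
#' @param sbp,dbp blood-pressure cutoffs in mmHg.
#' @param glucose fasting-glucose cutoff in mg/dl.
#' @param tg triglyceride cutoff in mg/dl.
#' @param hdl_male,hdl_female HDL cutoffs in mg/dl (reduced when `<=`).
#' @return an object of class `mets_criteria`.
#' @export
mets_criteria <- function(waist_male = 90, waist_female = 85,
                          sbp = 130, dbp = 85,
                          glucose = 100, tg = 150,
                          hdl_male = 40, hdl_female = 50) {
  crit <- list(waist_male = waist_male, waist_female = waist_female,
               sbp = sbp, dbp = dbp, glucose = glucose, tg = tg,
               hdl_male = hdl_male, hdl_female = hdl_female)
  if (any(unlist(crit) <= 0)) stop("all criteria must be positive")
  structure(crit, class = "mets_criteria")
}

#' Risk-factor flags and MetS label
#'
#' Applies the five diagnostic criteria to each participant. All four
#' "elevated" factors use inclusive `>=`; reduced HDL uses inclusive `<=`,
#' exactly as the criteria are stated.
#'
#' @param records data frame with columns `sex` ("M"/"F"), `waist`, `sbp`,
#'   `dbp`, `glucose`, `triglycerides`, `hdl`.
#' @param criteria a [mets_criteria()] object.
#' @return data frame with logical columns `abdominal_obesity`, `elevated_bp`,
#'   `elevated_glucose`, `elevated_tg`, `reduced_hdl`, integer `count`
#'   (0--5) and logical `mets` (`count >= 3`).
#' @export
risk_factors <- function(records, criteria = mets_criteria()) {
  stop_missing(records,
               c("sex", "waist", "sbp", "dbp", "glucose", "triglycerides",
                 "hdl"))
  if (!all(records$sex %in% c("M", "F"))) {
    stop("sex must be coded 'M' or 'F'")
  }
  male <- records$sex == "M"
  waist_cut <- ifelse(male, criteria$waist_male, criteria$waist_female)
  hdl_cut <- ifelse(male, criteria$hdl_male, criteria$hdl_female)
  out <- data.frame(
    abdominal_obesity = records$waist >= waist_cut,
    elevated_bp = records$sbp >= criteria$sbp | records$dbp >= criteria$dbp,
    elevated_glucose = records$glucose >= criteria$glucose,
    elevated_tg = records$triglycerides >= criteria$tg,
    reduced_hdl = records$hdl <= hdl_cut
  )
  out$count <- rowSums(out)
  out$mets <- out$count >= 3
  out
}

#' Diagnose MetS
#'
#' @inheritParams risk_factors
#' @return logical vector, `TRUE` where at least three risk factors are met.
#' @export
diagnose <- function(records, criteria = mets_criteria()) {
  risk_factors(records, criteria)$mets
}

#' MetS prevalence of a cohort
#'
#' @inheritParams risk_factors
#' @return fraction of diagnosed participants in `[0, 1]`.
#' @export
prevalence <- function(records, criteria = mets_criteria()) {
  if (nrow(records) == 0) stop("prevalence of an empty cohort is undefined")
  mean(diagnose(records, criteria))
}

#' Append diagnosis columns to a cohort
#'
#' Convenience wrapper adding `rf_count` and `mets` (0/1) columns.
#'
#' @inheritParams risk_factors
#' @return `records` with two extra columns.
#' @export
label_cohort <- function(records, criteria = mets_criteria()) {
  rf <- risk_factors(records, criteria)
  records$rf_count <- rf$count
  records$mets <- as.integer(rf$mets)
  records
}
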