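#' Criterion-scaled feature specification
#'
#' Each scaled feature maps a raw measurement x through the elliot sigmoid of
#' its deviation from a diagnostic criterion c:
#' `f(z) = 0.5 * z / (1 + |z|) + 0.5` with `z = (x - c) / denom`.
#' For waist circumference the denominator is `0.1 * c` (10% of the
#' criterion); for blood pressure the criterion in the denominator is replaced
#' by 45 (the nominal systolic-diastolic gap), giving `0.1 * 45 = 4.5`.
#'
#' @param c diagnostic criterion, in the units of x.
#' @param denom scale of the deviation, same units; must be positive.
#' @return a `scaled_spec` object.
#' @export
scaled_spec <- function(c, denom) {
  stopifnot(is.numeric(c), is.numeric(denom))
  if (denom <= 0) stop("denom must be positive")
  structure(list(c = c, denom = denom), class = "scaled_spec")
}

#' Built-in criterion specs
#'
#' `spec_sbp()`/`spec_dbp()` use criteria 130/85 mmHg with denominator 4.5;
#' `spec_wc("M")`/`spec_wc("F")` use 90/85 cm with denominator 0.1 * c.
#'
#' @param sex "M" or "F".
#' @return a [scaled_spec()].
#' @export
spec_sbp <- function() scaled_spec(130, 4.5)

#' @rdname spec_sbp
#' @export
spec_dbp <- function() scaled_spec(85, 4.5)

#' @rdname spec_sbp
#' @export
spec_wc <- function(sex) {
  if (length(sex) != 1 || !sex %in% c("M", "F")) {
    stop("sex must be 'M' or 'F'")
  }
  if (sex == "M") scaled_spec(90, 9) else scaled_spec(85, 8.5)
}

#' Elliot-sigmoid criterion scaling
#'
#' Maps a measurement into (0, 1): 0.5 exactly at the criterion, saturating
#' towards 0/1 away from it, most sensitive near the criterion. The interval
#' `[0.25, 0.75]` corresponds exactly to `x` within one denominator of the
#' criterion.
#'
#' @param x numeric measurement(s).
#' @param spec a [scaled_spec()].
#' @return values in the open interval (0, 1).
#' @export
elliot_scale <- function(x, spec) {
  if (!all(is.finite(x))) stop("elliot_scale: x must be finite")
  z <- (x - spec$c) / spec$denom
  0.5 * z / (1 + abs(z)) + 0.5
}

#' Inverse of the elliot scaling
#'
#' Used to annotate risk-map axes with raw cm / mmHg values.
#'
#' @param f scaled values, strictly inside (0, 1).
#' @param spec a [scaled_spec()].
#' @return raw measurement x with `elliot_scale(x, spec) == f`.
#' @export
inverse_elliot <- function(f, spec) {
  if (any(f <= 0 | f >= 1)) stop("inverse_elliot: f must lie in (0, 1)")
  u <- f - 0.5
  z <- u / (0.5 - abs(u))
  spec$c + spec$denom * z
}

#' Scaled blood-pressure feature BP
#'
#' The larger of the scaled systolic and scaled diastolic values,
#' `max(SBP, DBP)` on the (0, 1) scale.
#'
#' @param sbp,dbp pressures in mmHg (positive).
#' @return BP in (0, 1).
#' @export
scaled_bp <- function(sbp, dbp) {
  if (any(sbp <= 0) || any(dbp <= 0)) stop("pressures must be positive")
  pmax(elliot_scale(sbp, spec_sbp()), elliot_scale(dbp, spec_dbp()))
}

#' Scaled waist feature WC
#'
#' @param waist waist circumference in cm (positive).
#' @param sex vector of "M"/"F".
#' @return WC in (0, 1).
#' @export
scaled_wc <- function(waist, sex) {
  if (any(waist <= 0)) stop("waist must be positive")
  if (!all(sex %in% c("M", "F"))) stop("unknown sex code")
  out <- numeric(length(waist))
  m <- sex == "M"
  if (any(m)) out[m] <- elliot_scale(waist[m], spec_wc("M"))
  if (any(!m)) out[!m] <- elliot_scale(waist[!m], spec_wc("F"))
  out
}

#' BP/WC combination features
#'
#' The second-stage synthetic features: sum, product, difference, and the
#' shifted product `max(BP * WC - 0.25, 0)` which is zero until both sit at
#' their criteria.
#'
#' @param BP,WC scaled features in (0, 1).
#' @return data frame with `BPWC_add`, `BPWC_mul`, `BPWC_dif`, `BPWC_con`.
#' @export
bpwc_features <- function(BP, WC) {
  if (any(BP <= 0 | BP >= 1 | WC <= 0 | WC >= 1)) {
    stop("BP and WC must lie in (0, 1)")
  }
  data.frame(BPWC_add = BP + WC,
             BPWC_mul = BP * WC,
             BPWC_dif = BP - WC,
             BPWC_con = pmax(BP * WC - 0.25, 0))
}

#' Classical anthropometric indices
#'
#' The ten body-shape indices plus the bWC interaction. Formulas:
#' * BMI = weight(kg) / height(m)^2
#' * BFP = 0.567 waist + 0.101 age - 31.8 (male);
#'         0.439 waist + 0.221 age - 9.4 (female)
#' * WHR = waist / hip; WHtR = waist / height (both in cm)
#' * BRI = 364.2 - 365.5 sqrt(1 - (waist / (pi height))^2)
#' * ABSI = waist(m) / (BMI^(2/3) height(m)^(1/2))
#' * CUN_BAE = -44.988 + 0.503 age + 10.689 sex + 3.172 BMI - 0.026 BMI^2 +
#'   0.181 BMI sex - 0.02 BMI age - 0.005 BMI^2 sex + 0.00021 BMI^2 age,
#'   sex coded male 0 / female 1
#' * C_INDEX = waist(m) / (0.109 sqrt(weight / height(m)))  (conicity index)
#' * AVI = (2 waist^2 + 0.7 (waist - hip)^2) / 1000  (cm)
#' * BAI = 100 hip(m) / height(m)^1.5 - 18
#' * bWC = BMI * WC (scaled waist interaction)
#'
#' @param records data frame with `sex`, `age`, `height` (cm), `weight` (kg),
#'   `waist` (cm), `hip` (cm).
#' @return data frame of the eleven indices.
#' @export
anthropometric_indices <- function(records) {
  stop_missing(records, c("sex", "age", "height", "weight", "waist", "hip"))
  if (any(records$height <= 0 | records$weight <= 0 |
            records$waist <= 0 | records$hip <= 0)) {
    stop("height, weight, waist and hip must be positive")
  }
  male <- records$sex == "M"
  h_m <- records$height / 100
  waist_m <- records$waist / 100
  hip_m <- records$hip / 100
  bmi <- records$weight / h_m^2
  bfp <- ifelse(male,
                0.567 * records$waist + 0.101 * records$age - 31.8,
                0.439 * records$waist + 0.221 * records$age - 9.4)
  radicand <- 1 - (records$waist / (pi * records$height))^2
  if (any(radicand < 0)) {
    stop("BRI undefined: waist exceeds pi * height for some record")
  }
  sex01 <- as.numeric(!male) # male 0, female 1
  data.frame(
    BMI = bmi,
    BFP = bfp,
    WHR = records$waist / records$hip,
    WHtR = records$waist / records$height,
    BRI = 364.2 - 365.5 * sqrt(radicand),
    ABSI = waist_m / (bmi^(2 / 3) * sqrt(h_m)),
    CUN_BAE = -44.988 + 0.503 * records$age + 10.689 * sex01 +
      3.172 * bmi - 0.026 * bmi^2 + 0.181 * bmi * sex01 -
      0.02 * bmi * records$age - 0.005 * bmi^2 * sex01 +
      0.00021 * bmi^2 * records$age,
    C_INDEX = waist_m / (0.109 * sqrt(records$weight / h_m)),
    AVI = (2 * records$waist^2 + 0.7 * (records$waist - records$hip)^2) / 1000,
    BAI = 100 * hip_m / h_m^1.5 - 18,
    bWC = bmi * scaled_wc(records$waist, records$sex)
  )
}

#' Names of the criterion-scaled synthetic family
#'
#' The features built from waist circumference, blood pressure and sex only.
#'
#' @return character vector of feature names.
#' @export
bpwc_family <- function() {
  c("SBP", "DBP", "BP", "WC", "BPWC_add", "BPWC_mul", "BPWC_dif", "BPWC_con")
}

#' Feature families
#'
#' Partition of the feature names into the three families used by the
#' three-round selection: anthropometric (raw basics + classical body-shape
#' indices), survey-based (lifestyle covariates present in the cohort), and
#' proposed synthetics (the criterion-scaled family plus bWC).
#'
#' @param records a cohort data frame (to discover lifestyle columns).
#' @return named list of character vectors.
#' @export
feature_families <- function(records) {
  base_cols <- c("id", "sex", "age", "height", "weight", "waist", "hip",
                 "sbp", "dbp", "glucose", "triglycerides", "hdl",
                 "rf_count", "mets")
  lifestyle <- setdiff(names(records), base_cols)
  list(
    anthropometric = c("sex01", "age", "height", "weight", "waist", "hip",
                       "BMI", "BFP", "WHR", "WHtR", "BRI", "ABSI", "CUN_BAE",
                       "C_INDEX", "AVI", "BAI"),
    survey = lifestyle,
    proposed = c(bpwc_family(), "bWC")
  )
}

# Raw measurements entering each synthesized feature; raw features map to
# themselves. Used to count distinct raw inputs of a final model.
synthesis_map <- function() {
  list(
    SBP = "sbp", DBP = "dbp",
    BP = c("sbp", "dbp"),
    WC = c("waist", "sex"),
    BPWC_add = c("waist", "sex", "sbp", "dbp"),
    BPWC_mul = c("waist", "sex", "sbp", "dbp"),
    BPWC_dif = c("waist", "sex", "sbp", "dbp"),
    BPWC_con = c("waist", "sex", "sbp", "dbp"),
    bWC = c("waist", "sex", "weight", "height"),
    BMI = c("weight", "height"),
    BFP = c("waist", "age", "sex"),
    WHR = c("waist", "hip"),
    WHtR = c("waist", "height"),
    BRI = c("waist", "height"),
    ABSI = c("waist", "weight", "height"),
    CUN_BAE = c("age", "sex", "weight", "height"),
    C_INDEX = c("waist", "weight", "height"),
    AVI = c("waist", "hip"),
    BAI = c("hip", "height"),
    sex01 = "sex"
  )
}

#' Count distinct raw measurements behind a feature set
#'
#' @param features character vector of feature names.
#' @return integer count of distinct raw inputs.
#' @export
raw_feature_count <- function(features) {
  map <- synthesis_map()
  raw <- unlist(lapply(features, function(f) map[[f]] %||% f))
  length(unique(raw))
}

#' Assemble a feature matrix
#'
#' Computes any requested subset of the known features plus lifestyle
#' covariates carried in the cohort, with a provenance tag per feature
#' (`raw`, `synthetic-known` for the classical indices, `synthetic-novel`
#' for the criterion-scaled family).
#'
#' @param records cohort data frame.
#' @param feature_names character vector; unknown names raise an error
#'   listing the valid ones.
#' @return a data frame of features, with attributes `provenance` (named
#'   character vector) and `sex` (the cohort's sex column).
#' @export
build_feature_matrix <- function(records, feature_names) {
  fams <- feature_families(records)
  known <- unique(c(unlist(fams, use.names = FALSE)))
  bad <- setdiff(feature_names, known)
  if (length(bad) > 0) {
    stop(sprintf("unknown feature(s): %s. Valid names: %s",
                 paste(bad, collapse = ", "),
                 paste(sort(known), collapse = ", ")))
  }
  n <- nrow(records)
  need_anthro <- any(feature_names %in%
                       c("BMI", "BFP", "WHR", "WHtR", "BRI", "ABSI",
                         "CUN_BAE", "C_INDEX", "AVI", "BAI", "bWC"))
  anthro <- if (need_anthro) anthropometric_indices(records) else NULL
  need_scaled <- any(feature_names %in% bpwc_family())
  if (need_scaled) {
    SBPv <- elliot_scale(records$sbp, spec_sbp())
    DBPv <- elliot_scale(records$dbp, spec_dbp())
    BPv <- pmax(SBPv, DBPv)
    WCv <- scaled_wc(records$waist, records$sex)
    combos <- bpwc_features(BPv, WCv)
  }
  cols <- lapply(feature_names, function(f) {
    switch(f,
      sex01 = as.numeric(records$sex == "F"),
      SBP = SBPv, DBP = DBPv, BP = BPv, WC = WCv,
      BPWC_add = combos$BPWC_add, BPWC_mul = combos$BPWC_mul,
      BPWC_dif = combos$BPWC_dif, BPWC_con = combos$BPWC_con,
      if (!is.null(anthro) && f %in% names(anthro)) anthro[[f]]
      else records[[f]]
    )
  })
  names(cols) <- feature_names
  out <- if (length(cols) > 0) as.data.frame(cols) else
    as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  if (ncol(out) > 0 && !all(vapply(out, function(x) all(is.finite(x)),
                                   logical(1)))) {
    stop("feature matrix contains non-finite values")
  }
  prov <- vapply(feature_names, function(f) {
    if (f %in% c(bpwc_family(), "bWC")) "synthetic-novel"
    else if (f %in% c("BMI", "BFP", "WHR", "WHtR", "BRI", "ABSI", "CUN_BAE",
                      "C_INDEX", "AVI", "BAI")) "synthetic-known"
    else "raw"
  }, character(1))
  attr(out, "provenance") <- prov
  attr(out, "sex") <- records$sex
  out
}
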