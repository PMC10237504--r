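#' Default group marginals for the synthetic cohort
#'
#' Mean and SD per variable, separately for participants without and with
#' MetS, mirroring the published characteristics of a large Korean
#' health-checkup population (ages 40--69, overall MetS prevalence 13.6%):
#' e.g. systolic blood pressure 118.5 +/- 13.3 (without) vs 132.5 +/- 14.4
#' (with), waist 78.3 +/- 7.7 vs 87.9 +/- 7.4. Height, weight and hip are not
#' part of that table; sex-specific values typical of middle-aged Korean
#' checkup populations are used.
#'
#' @return nested list with `without` and `with` components.
#' @export
default_marginals <- function() {
  common <- list(
    height = list(M = c(167, 6), F = c(155, 5.5)),
    weight = list(M = c(68, 9), F = c(58, 8)),
    hip = list(M = c(94.5, 5.5), F = c(93.5, 6))
  )
  list(
    without = c(list(
      male_frac = 17424 / 60775,
      age = c(50.3, 7.5),
      sbp = c(118.5, 13.3),
      dbp = c(73.9, 9.2),
      waist = c(78.3, 7.7),
      glucose = c(89.6, 11.8),
      triglycerides = c(102.4, 61.9),
      hdl = c(56.9, 12.7)
    ), common),
    with = c(list(
      male_frac = 4228 / 9595,
      age = c(52.8, 7.9),
      sbp = c(132.5, 14.4),
      dbp = c(82.3, 9.7),
      waist = c(87.9, 7.4),
      glucose = c(102.7, 23.5),
      triglycerides = c(211.7, 126.1),
      hdl = c(44.6, 9.4)
    ), common)
  )
}

#' Wide physiologic bounds used for truncation and eligibility filtering
#'
#' @return named list of `c(lower, upper)` bounds.
#' @export
default_bounds <- function() {
  list(age = c(40, 69), height = c(130, 200), weight = c(30, 150),
       waist = c(50, 150), hip = c(60, 160), sbp = c(70, 250),
       dbp = c(40, 150), glucose = c(50, 400), triglycerides = c(20, 1500),
       hdl = c(10, 150))
}

# Lifestyle covariates: pure noise by default, loosely matched to plausible
# ranges (energy fractions in %, intakes in g/day, non_smoker a 0/1 flag).
default_lifestyle <- function() {
  list(
    carbohydrate_energy = list(mean = 65, sd = 7, lo = 30, hi = 90),
    fat_energy = list(mean = 18, sd = 5, lo = 3, hi = 45),
    non_smoker = list(p = 0.75),
    grain = list(mean = 300, sd = 90, lo = 0, hi = 900),
    retinol = list(mean = 400, sd = 180, lo = 0, hi = 2000),
    kimchi = list(mean = 110, sd = 55, lo = 0, hi = 600),
    green_vegetables = list(mean = 80, sd = 40, lo = 0, hi = 500),
    leaf_tea = list(mean = 30, sd = 35, lo = 0, hi = 400),
    lettuce = list(mean = 15, sd = 14, lo = 0, hi = 200)
  )
}

#' Specification of a synthetic cohort
#'
#' @param n number of participants.
#' @param target_prevalence MetS fraction in (0, 1); default 0.136.
#' @param group_marginals per-group mean/SD list, see [default_marginals()].
#' @param signal_strength named numeric vector; shifts the named lifestyle
#'   covariate's mean by `effect * SD` in the MetS group (default: none, all
#'   lifestyle covariates are pure noise).
#' @param latent_loading optional correlation hook: a latent standard-normal
#'   metabolic factor is added with this loading (in SD units) to waist, sbp,
#'   dbp, glucose and triglycerides and subtracted from HDL. Default 0
#'   (independent marginals).
#' @param seed integer RNG seed.
#' @param max_attempts cap on rejection-sampling rounds per group.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n, target_prevalence = 0.136,
                        group_marginals = default_marginals(),
                        signal_strength = NULL,
                        latent_loading = 0,
                        seed = 1L, max_attempts = 200L) {
  if (n < 0) stop("n must be non-negative")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must lie in (0, 1)")
  }
  for (g in c("without", "with")) {
    for (v in c("age", "sbp", "dbp", "waist", "glucose", "triglycerides",
                "hdl")) {
      if (group_marginals[[g]][[v]][2] <= 0) {
        stop(sprintf("SD of %s (%s group) must be positive", v, g))
      }
    }
  }
  b <- default_bounds()
  adjusted <- lapply(group_marginals, function(gm) {
    out <- list()
    for (v in c("age", "sbp", "dbp", "waist", "glucose", "triglycerides",
                "hdl")) {
      out[[v]] <- match_truncnorm(gm[[v]][1], gm[[v]][2], b[[v]][1],
                                  b[[v]][2])
    }
    for (v in c("height", "weight", "hip")) {
      out[[v]] <- lapply(gm[[v]], function(ms) {
        match_truncnorm(ms[1], ms[2], b[[v]][1], b[[v]][2])
      })
    }
    out
  })
  structure(list(n = as.integer(n), target_prevalence = target_prevalence,
                 group_marginals = group_marginals,
                 adjusted_marginals = adjusted,
                 signal_strength = signal_strength,
                 latent_loading = latent_loading,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "cohort_spec")
}

# Truncated-normal draws by inverse-CDF transform (exact, vectorised).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Moments of a normal truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = if (is.finite(v) && v > 0) sqrt(v) else NaN)
}

# Parent (mu, sigma) such that the truncated distribution has the requested
# mean and SD; truncation at a bound otherwise biases the realised moments
# (e.g. a heavy-SD triglyceride marginal against its lower physiologic
# bound).
match_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    if (!all(is.finite(mo))) return(1e9)
    (mo[1] - mean)^2 / sd^2 + (mo[2] - sd)^2 / sd^2
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-12, maxit = 2000))
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

#' Draw candidates from one group's marginals (pre-rejection)
#'
#' The raw marginal sampler underlying [generate_cohort()]: independent
#' truncated-normal draws per variable from the group's configured mean/SD,
#' sex-specific body-frame variables, diastolic pressure redrawn until below
#' systolic, and noise lifestyle covariates. No diagnosis consistency is
#' enforced here; [generate_cohort()] adds the criterion rejection step.
#'
#' @param spec a [cohort_spec()].
#' @param group "without" or "with".
#' @param m number of candidates.
#' @return data frame of candidate records (no `id` column).
#' @export
sample_group_marginals <- function(spec, group, m) {
  group <- match.arg(group, c("without", "with"))
  gm <- spec$group_marginals[[group]]
  adj <- spec$adjusted_marginals[[group]]
  b <- default_bounds()
  if (m == 0) return(NULL)
  sex <- ifelse(stats::runif(m) < gm$male_frac, "M", "F")
  draw <- function(v) rtrunc_norm(m, adj[[v]]["mu"], adj[[v]]["sigma"],
                                  b[[v]][1], b[[v]][2])
  draw_sexed <- function(v) {
    out <- numeric(m)
    for (s in c("M", "F")) {
      idx <- sex == s
      if (any(idx)) {
        out[idx] <- rtrunc_norm(sum(idx), adj[[v]][[s]]["mu"],
                                adj[[v]][[s]]["sigma"],
                                b[[v]][1], b[[v]][2])
      }
    }
    out
  }
  rec <- data.frame(
    sex = sex,
    age = pmin(pmax(round(draw("age")), b$age[1]), b$age[2]),
    height = draw_sexed("height"),
    weight = draw_sexed("weight"),
    waist = draw("waist"),
    hip = draw_sexed("hip"),
    sbp = draw("sbp"),
    dbp = draw("dbp"),
    glucose = draw("glucose"),
    triglycerides = draw("triglycerides"),
    hdl = draw("hdl")
  )
  if (spec$latent_loading != 0) {
    lat <- stats::rnorm(m)
    lam <- spec$latent_loading
    for (v in c("waist", "sbp", "dbp", "glucose", "triglycerides")) {
      rec[[v]] <- pmin(pmax(rec[[v]] + lam * gm[[v]][2] * lat,
                            b[[v]][1]), b[[v]][2])
    }
    rec$hdl <- pmin(pmax(rec$hdl - lam * gm$hdl[2] * lat,
                         b$hdl[1]), b$hdl[2])
  }
  # enforce sbp > dbp by redrawing offending diastolic values
  for (i in 1:50) {
    bad <- rec$dbp >= rec$sbp
    if (!any(bad)) break
    rec$dbp[bad] <- rtrunc_norm(sum(bad), adj$dbp["mu"], adj$dbp["sigma"],
                                b$dbp[1], b$dbp[2])
  }
  rec$dbp <- pmin(rec$dbp, rec$sbp - 0.5) # guard for stragglers
  ls <- default_lifestyle()
  sig <- spec$signal_strength
  for (nm in names(ls)) {
    p <- ls[[nm]]
    if (!is.null(p$p)) {
      rec[[nm]] <- as.numeric(stats::runif(m) < p$p)
    } else {
      mu <- p$mean
      if (group == "with" && !is.null(sig) && nm %in% names(sig)) {
        mu <- mu + sig[[nm]] * p$sd
      }
      rec[[nm]] <- rtrunc_norm(m, mu, p$sd, p$lo, p$hi)
    }
  }
  rec
}

#' Generate a criterion-consistent synthetic cohort
#'
#' Two-component mixture: `round(n * target_prevalence)` records are drawn
#' from the with-MetS marginals and the rest from the without-MetS marginals,
#' each candidate kept only if its diagnosis (under `criteria`) matches its
#' generating group (rejection sampling). Row order is a random permutation of
#' the two groups. Deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param criteria diagnostic criteria, see [mets_criteria()].
#' @return data frame of `n` participant records with column order
#'   `id, sex, age, height, weight, waist, hip, sbp, dbp, glucose,
#'   triglycerides, hdl, <lifestyle...>`.
#' @export
generate_cohort <- function(spec, criteria = mets_criteria()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_pos <- round(spec$n * spec$target_prevalence)
  n_neg <- spec$n - n_pos
  draw_group <- function(group, want) {
    kept <- NULL
    need <- want
    attempts <- 0L
    while (need > 0) {
      attempts <- attempts + 1L
      if (attempts > spec$max_attempts) {
        stop(sprintf(
          "rejection sampling for the %s-MetS group exceeded %d attempts; marginals appear infeasible",
          group, spec$max_attempts))
      }
      cand <- sample_group_marginals(spec, group, max(need * 2L, 100L))
      ok <- diagnose(cand, criteria) == (group == "with")
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
      kept <- rbind(kept, cand)
      need <- want - NROW(kept)
    }
    kept
  }
  pos <- draw_group("with", n_pos)
  neg <- draw_group("without", n_neg)
  out <- rbind(pos, neg)
  if (spec$n == 0) {
    out <- sample_group_marginals(spec, "without", 1)[0, , drop = FALSE]
  } else {
    out <- out[sample.int(nrow(out)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out <- cbind(id = sprintf("P%06d", seq_len(nrow(out))), out)
  out
}

#' Eligibility and completeness filter
#'
#' Drops records aged 70 or older, records with any missing required field,
#' and records violating the configured outlier bounds. Order preserved.
#'
#' @param records cohort data frame.
#' @param bounds named list of `c(lower, upper)`; see [default_bounds()].
#' @return filtered data frame (possibly empty).
#' @export
filter_eligible <- function(records, bounds = default_bounds()) {
  required <- c("sex", "age", "height", "weight", "waist", "hip", "sbp",
                "dbp", "glucose", "triglycerides", "hdl")
  keep <- rep(TRUE, nrow(records))
  for (f in required) {
    keep <- keep & !is.na(records[[f]])
  }
  keep <- keep & !is.na(records$age) & records$age < 70
  for (v in names(bounds)) {
    if (v %in% names(records)) {
      ok <- records[[v]] >= bounds[[v]][1] & records[[v]] <= bounds[[v]][2]
      ok[is.na(ok)] <- FALSE
      keep <- keep & ok
    }
  }
  records[keep, , drop = FALSE]
}

#' Per-group cohort summary
#'
#' Means and SDs of each numeric field, overall and split by diagnosed MetS
#' status, plus sex counts and the mean risk-factor count. The SD of a
#' single-record group is reported as `NA` (undefined), not 0.
#'
#' @param records non-empty cohort data frame.
#' @param criteria diagnostic criteria.
#' @return data frame, one row per variable and group.
#' @export
cohort_summary <- function(records, criteria = mets_criteria()) {
  if (nrow(records) == 0) stop("cannot summarise an empty cohort")
  rf <- risk_factors(records, criteria)
  groups <- list(all = rep(TRUE, nrow(records)),
                 without = !rf$mets, with = rf$mets)
  numvars <- c("age", "height", "weight", "waist", "hip", "sbp", "dbp",
               "glucose", "triglycerides", "hdl")
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (!any(idx)) next
    ng <- sum(idx)
    for (v in numvars) {
      x <- records[[v]][idx]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, n = ng, mean = mean(x),
        sd = if (ng > 1) stats::sd(x) else NA_real_)
    }
    rows[[length(rows) + 1]] <- data.frame(
      group = g, variable = "rf_count", n = ng, mean = mean(rf$count[idx]),
      sd = if (ng > 1) stats::sd(rf$count[idx]) else NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, variable = "male_n", n = ng,
      mean = sum(records$sex[idx] == "M"), sd = NA_real_)
  }
  do.call(rbind, rows)
}

#' Write / read a cohort as CSV
#'
#' One header row, sex coded "M"/"F", missing values as empty fields.
#'
#' @param records cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character", sex = "character"),
                  na.strings = "")
}
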