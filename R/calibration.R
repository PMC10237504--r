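#' Platt scaling
#'
#' Fits the sigmoid recalibration map `P(y = 1 | f) = 1 / (1 + exp(A f + B))`
#' by maximum likelihood (the binomial log-likelihood is optimised by
#' iteratively reweighted least squares, i.e. damped Newton steps, to
#' tolerance 1e-8).
#'
#' @param scores classifier outputs on an independent fitting set.
#' @param labels binary labels, both classes present.
#' @return a `platt_params` object with coefficients `A` and `B`.
#' @export
platt_fit <- function(scores, labels) {
  y <- as.numeric(labels)
  if (all(y == 0) || all(y == 1)) {
    stop("platt_fit needs both classes in the fitting set")
  }
  fit <- stats::glm(y ~ scores, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  co <- stats::coef(fit)
  # glm parameterises P = 1/(1 + exp(-(b0 + b1 f))); convert to A f + B form
  structure(list(A = unname(-co[2]), B = unname(-co[1])),
            class = "platt_params")
}

#' @rdname platt_fit
#' @param params fitted `platt_params`.
#' @param f new scores.
#' @return calibrated probabilities in (0, 1).
#' @export
platt_apply <- function(params, f) {
  1 / (1 + exp(params$A * f + params$B))
}

#' Isotonic recalibration
#'
#' Least-squares monotone fit of labels on scores via pool-adjacent-violators
#' ([stats::isoreg()]). Evaluation outside the fitted score range clamps to
#' the end values; inside, the fitted step/interpolated values are used.
#'
#' @param scores classifier outputs on an independent fitting set.
#' @param labels binary labels, both classes present.
#' @return an `isotonic_map` object.
#' @export
isotonic_fit <- function(scores, labels) {
  y <- as.numeric(labels)
  if (all(y == 0) || all(y == 1)) {
    stop("isotonic_fit needs both classes in the fitting set")
  }
  o <- order(scores, y) # secondary key makes ties deterministic
  ir <- stats::isoreg(scores[o], y[o])
  structure(list(x = ir$x, yf = ir$yf), class = "isotonic_map")
}

#' @rdname isotonic_fit
#' @param map fitted `isotonic_map`.
#' @param f new scores.
#' @export
isotonic_apply <- function(map, f) {
  stats::approx(map$x, map$yf, xout = f, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Undersampling bias correction
#'
#' For a model trained on a 1:1 undersampled set, the predicted probability
#' `p_s` overstates the true probability. With `beta` the probability that a
#' negative instance was retained by the undersampling, the bias-corrected
#' probability is `p' = beta * p_s / (beta * p_s - p_s + 1)`. It is the
#' identity at `beta = 1`, fixes the endpoints 0 and 1, and is strictly
#' increasing in `p_s`.
#'
#' @param p_s predicted probabilities in `[0, 1]`.
#' @param beta retention probability in (0, 1].
#' @return corrected probabilities in `[0, 1]`.
#' @export
pozzolo_correct <- function(p_s, beta) {
  if (any(p_s < 0 | p_s > 1)) stop("p_s must lie in [0, 1]")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  beta * p_s / (beta * p_s - p_s + 1)
}

#' Inverse of the undersampling correction
#'
#' @param p corrected probabilities.
#' @param beta retention probability.
#' @return the uncorrected `p_s` with `pozzolo_correct(p_s, beta) == p`.
#' @export
pozzolo_invert <- function(p, beta) {
  p / (beta - beta * p + p)
}

#' Decision threshold after undersampling correction
#'
#' The optimal threshold on the corrected probability equals the probability
#' of drawing a positive from the full (pre-undersampling) training data,
#' i.e. its positive fraction.
#'
#' @param labels_full_training binary labels of the full training pool.
#' @return threshold in (0, 1).
#' @export
pozzolo_threshold <- function(labels_full_training) {
  y <- as.logical(labels_full_training)
  if (length(y) == 0) stop("empty training labels")
  if (all(y) || !any(y)) stop("threshold undefined for single-class data")
  mean(y)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and outcomes; lower is
#' better.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary outcomes, same length.
#' @return non-negative score.
#' @export
brier_score <- function(p, y) {
  if (length(p) != length(y)) stop("length mismatch")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  mean((as.numeric(y) - p)^2)
}

#' Spiegelhalter's calibration z-test
#'
#' `z = sum((y - p)(1 - 2p)) / sqrt(sum((1 - 2p)^2 p (1 - p)))`; under the
#' null of perfect calibration z is asymptotically standard normal, and
#' |z| > 1.96 indicates miscalibration at the 5% level. Predictions exactly
#' 0 or 1 are clipped to `[1e-6, 1 - 1e-6]` to keep the variance terms
#' positive.
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @return list with `z` and two-sided `p_value`.
#' @export
spiegelhalter_z <- function(p, y) {
  if (length(p) != length(y)) stop("length mismatch")
  p <- clip01(p)
  y <- as.numeric(y)
  num <- sum((y - p) * (1 - 2 * p))
  v <- sum((1 - 2 * p)^2 * p * (1 - p))
  if (v <= 0) stop("Spiegelhalter statistic degenerate: zero variance (all predictions 0.5?)")
  z <- num / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Calibration (reliability) curve
#'
#' Equal-width bins over `[0, 1]`; per non-empty bin the mean predicted
#' probability and the observed positive fraction.
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @param bins number of bins (default 10).
#' @return data frame with `bin`, `mean_pred`, `frac_pos`, `n`.
#' @export
calibration_curve <- function(p, y, bins = 10) {
  if (length(p) == 0) stop("empty input")
  idx <- pmin(pmax(ceiling(p * bins), 1), bins)
  y <- as.numeric(y)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin = b, mean_pred = mean(p[sel]), frac_pos = mean(y[sel]),
               n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Calibration report for one method
#'
#' @param method one of "none", "platt", "isotonic", "pozzolo".
#' @param p calibrated probabilities on the evaluation set.
#' @param y outcomes.
#' @param bins bins for the reliability curve.
#' @return a `calibration_report` list with Brier score, Spiegelhalter z and
#'   p-value, and the curve points.
#' @export
calibration_report <- function(method, p, y, bins = 10) {
  sz <- spiegelhalter_z(p, y)
  structure(list(method = method, brier = brier_score(p, y),
                 spiegelhalter_z = sz$z, spiegelhalter_p = sz$p_value,
                 curve = calibration_curve(p, y, bins)),
            class = "calibration_report")
}

#' Fit and compare calibration methods for a trained model
#'
#' Fits Platt and isotonic maps on an independent fitting set (naturally
#' prevalent, e.g. validation folds), applies the undersampling correction
#' analytically from `beta`, and evaluates every method on the evaluation
#' set. The preferred method is the lowest Brier score among methods whose
#' Spiegelhalter p-value exceeds 0.05 (larger p breaks Brier ties); if no
#' method clears 0.05 the lowest Brier wins with a warning.
#'
#' @param model a trained model (see [train_model()]).
#' @param fit_features,fit_labels independent calibration set.
#' @param eval_features,eval_labels evaluation set.
#' @param beta negative-retention probability of the model's undersampled
#'   training set.
#' @param methods subset of c("none", "platt", "isotonic", "pozzolo").
#' @return list with `best` (method name), `reports` (per method) and
#'   `calibrators` (functions mapping raw scores to calibrated
#'   probabilities).
#' @export
select_calibration <- function(model, fit_features, fit_labels,
                               eval_features, eval_labels, beta,
                               methods = c("platt", "isotonic", "pozzolo")) {
  fit_scores <- predict_prob(model, fit_features)
  eval_scores <- predict_prob(model, eval_features)
  calibrators <- list(none = function(s) s)
  if ("platt" %in% methods) {
    pp <- platt_fit(fit_scores, fit_labels)
    calibrators$platt <- function(s) platt_apply(pp, s)
  }
  if ("isotonic" %in% methods) {
    im <- isotonic_fit(fit_scores, fit_labels)
    calibrators$isotonic <- function(s) isotonic_apply(im, s)
  }
  if ("pozzolo" %in% methods) {
    calibrators$pozzolo <- function(s) pozzolo_correct(s, beta)
  }
  use <- intersect(c("none", "platt", "isotonic", "pozzolo"),
                   unique(c(methods)))
  reports <- lapply(use, function(m) {
    calibration_report(m, calibrators[[m]](eval_scores), eval_labels)
  })
  names(reports) <- use
  ok <- vapply(reports, function(r) r$spiegelhalter_p > 0.05, logical(1))
  briers <- vapply(reports, function(r) r$brier, numeric(1))
  pvals <- vapply(reports, function(r) r$spiegelhalter_p, numeric(1))
  cand <- if (any(ok)) which(ok) else {
    warning("no calibration method passed the Spiegelhalter test; ",
            "falling back to the lowest Brier score")
    seq_along(reports)
  }
  best <- cand[order(briers[cand], -pvals[cand])][1]
  list(best = names(reports)[best], reports = reports,
       calibrators = calibrators[use])
}
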