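test_that("Platt scaling recovers known sigmoid parameters", {
  set.seed(31)
  n <- 5000
  f <- rnorm(n, 0, 2)
  A <- -2
  B <- 2
  y <- rbinom(n, 1, 1 / (1 + exp(A * f + B)))
  pp <- platt_fit(f, y)
  expect_lt(abs(pp$A - A) / abs(A), 0.1)
  expect_lt(abs(pp$B - B) / abs(B), 0.1)
  p <- platt_apply(pp, c(-8, 0, 8))
  expect_true(all(p > 0 & p < 1))
  # symmetric scores/labels calibrate to ~0.5 at the symmetry point
  f2 <- c(-rev(seq(0.1, 2, 0.1)), seq(0.1, 2, 0.1))
  y2 <- as.numeric(f2 > 0)
  pp2 <- suppressWarnings(platt_fit(f2, y2)) # separable by construction
  expect_equal(platt_apply(pp2, 0), 0.5, tolerance = 1e-6)
  expect_error(platt_fit(1:5, rep(1, 5)), "both classes")
})

test_that("isotonic regression pools adjacent violators and clamps", {
  # anti-monotone toy: PAV pools everything to the grand mean 0.5
  m <- isotonic_fit(1:4, c(1, 1, 0, 0))
  expect_equal(isotonic_apply(m, 1:4), rep(0.5, 4))
  # already monotone labels are interpolated exactly
  m2 <- isotonic_fit(1:4, c(0, 0, 1, 1))
  expect_equal(isotonic_apply(m2, 1:4), c(0, 0, 1, 1))
  # fitted values never decrease; out-of-range clamps to end values
  set.seed(32)
  s <- runif(300)
  y <- rbinom(300, 1, s)
  m3 <- isotonic_fit(s, y)
  expect_true(all(diff(m3$yf) >= -1e-12))
  expect_equal(isotonic_apply(m3, -1), m3$yf[1])
  expect_equal(isotonic_apply(m3, 2), m3$yf[length(m3$yf)])
  expect_error(isotonic_fit(1:3, c(0, 0, 0)), "both classes")
})

test_that("undersampling correction: identity, prevalence, endpoints, bijection", {
  p <- seq(0, 1, 0.05)
  expect_equal(pozzolo_correct(p, 1), p)
  # at p_s = 0.5 with beta = N+/N-, the corrected value is the prevalence
  npos <- 137
  nneg <- 863
  beta <- npos / nneg
  expect_equal(pozzolo_correct(0.5, beta), npos / (npos + nneg))
  expect_equal(pozzolo_correct(c(0, 1), 0.3), c(0, 1))
  # strictly increasing and invertible at machine precision
  expect_true(all(diff(pozzolo_correct(p, 0.2)) > 0))
  expect_equal(pozzolo_invert(pozzolo_correct(p, 0.137), 0.137), p,
               tolerance = 1e-12)
  expect_error(pozzolo_correct(1.5, 0.5), "\\[0, 1\\]")
  expect_error(pozzolo_correct(0.5, 0), "beta")
})

test_that("the corrected decision threshold is the full-data positive rate", {
  y <- c(rep(1, 137), rep(0, 863))
  expect_equal(pozzolo_threshold(y), 0.137)
  expect_equal(pozzolo_threshold(c(0, 1, 0, 1)), 0.5)
  expect_error(pozzolo_threshold(rep(1, 10)), "single-class")
  expect_error(pozzolo_threshold(numeric(0)), "empty")
})

test_that("Brier score is the mean squared error of the probabilities", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(brier_score(0.5, c(0, 1)), "length")
  # constant prediction at the prevalence scores ~ p(1-p)
  set.seed(33)
  y <- rbinom(20000, 1, 0.136)
  expect_equal(brier_score(rep(0.136, 20000), y), 0.136 * 0.864,
               tolerance = 0.01)
})

test_that("Spiegelhalter z matches hand computation and its null distribution", {
  sz <- spiegelhalter_z(c(0.2, 0.8), c(0, 1))
  # numerator -0.24, variance sum 0.1152
  expect_equal(sz$z, -0.24 / sqrt(0.1152))
  expect_equal(sz$z, -0.7071, tolerance = 1e-4)
  expect_equal(sz$p_value, 2 * pnorm(-abs(sz$z)))
  expect_error(spiegelhalter_z(rep(0.5, 4), c(0, 1, 0, 1)), "degenerate")
  # calibrated predictions give |z| < 1.96 about 95% of the time
  set.seed(34)
  p <- runif(2000, 0.05, 0.95)
  inside <- vapply(1:400, function(i) {
    y <- rbinom(2000, 1, p)
    abs(spiegelhalter_z(p, y)$z) < 1.96
  }, logical(1))
  expect_equal(mean(inside), 0.95, tolerance = 0.035)
})

test_that("calibration curve bins predictions against observed rates", {
  set.seed(35)
  p <- runif(20000)
  y <- rbinom(20000, 1, p)
  cc <- calibration_curve(p, y, bins = 10)
  expect_equal(nrow(cc), 10)
  expect_lt(max(abs(cc$mean_pred - cc$frac_pos)), 0.05)
  # all predictions in one bin -> single point
  cc1 <- calibration_curve(rep(0.55, 50), rbinom(50, 1, 0.5))
  expect_equal(nrow(cc1), 1)
  # overestimating predictor sits below the diagonal
  cc2 <- calibration_curve(pmin(p + 0.3, 0.999), y, bins = 10)
  expect_true(mean(cc2$frac_pos < cc2$mean_pred) > 0.8)
  expect_error(calibration_curve(numeric(0), numeric(0)), "empty")
})

test_that("select_calibration flags the raw undersampled model and fixes it", {
  ch <- small_cohort(6000, seed = 61)
  feats <- build_feature_matrix(ch, c("BPWC_add", "BPWC_mul", "BPWC_dif"))
  plan <- make_split_plan(ch, reps = 2, seed = 61)
  idx <- plan_indices(plan, ch$id)
  pool_i <- attr(idx, "pool")
  model <- train_model(model_spec("cart_tree", seed = 61),
                       feats[idx[[1]]$train, ], ch$mets[idx[[1]]$train])
  tr_pool <- setdiff(pool_i, idx[[1]]$validation)
  beta <- sum(ch$mets[tr_pool] == 1) / sum(ch$mets[tr_pool] == 0)
  # evaluate on a fresh naturally-prevalent cohort of 5,000
  ev <- label_cohort(generate_cohort(cohort_spec(5000, seed = 162)))
  fev <- build_feature_matrix(ev, c("BPWC_add", "BPWC_mul", "BPWC_dif"))
  sel <- select_calibration(model,
                            feats[idx[[1]]$validation, ],
                            ch$mets[idx[[1]]$validation],
                            fev, ev$mets,
                            beta = beta,
                            methods = c("none", "platt", "isotonic",
                                        "pozzolo"))
  # the raw 1:1-trained model overestimates: Spiegelhalter rejects it
  expect_lt(sel$reports$none$spiegelhalter_p, 0.05)
  # the undersampling correction restores calibration
  expect_gt(sel$reports$pozzolo$spiegelhalter_p, 0.05)
  expect_false(sel$best == "none")
  # corrected Brier beats the raw one
  expect_lt(sel$reports[[sel$best]]$brier, sel$reports$none$brier)
  # calibration-in-the-large for the selected method
  p_best <- sel$calibrators[[sel$best]](predict_prob(model, fev))
  obs <- mean(ev$mets)
  se2 <- 2 * sqrt(obs * (1 - obs) / nrow(ev))
  expect_lt(abs(mean(p_best) - obs), se2)
  # single candidate method is returned as best
  one <- select_calibration(model, feats[idx[[1]]$validation, ],
                            ch$mets[idx[[1]]$validation],
                            fev, ev$mets,
                            beta = beta, methods = "platt")
  expect_equal(one$best, "platt")
})
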