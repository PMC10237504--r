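# A tiny planted-signal design: one informative feature plus noise columns.
planted_design <- function(n = 600, p_noise = 9, seed = 1) {
  set.seed(seed)
  signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * signal))
  x <- as.data.frame(matrix(rnorm(n * p_noise), n, p_noise))
  names(x) <- sprintf("noise%02d", seq_len(p_noise))
  x$signal <- signal
  list(x = x[, sort(names(x)), drop = FALSE], y = y)
}

test_that("train_model validates inputs and is seed-deterministic", {
  d <- planted_design()
  expect_error(train_model(model_spec("logistic"), d$x[, 0], d$y), "empty")
  expect_error(train_model(model_spec("logistic"), d$x, rep(1, nrow(d$x))),
               "single-class")
  expect_error(model_spec("svm"), "unknown algorithm")
  expect_error(model_spec("cart_tree", list(depth = 3)),
               "unknown hyperparameter")
  for (algo in c("cart_tree", "random_forest", "gradient_boosted_trees")) {
    m1 <- train_model(model_spec(algo, seed = 5), d$x, d$y)
    m2 <- train_model(model_spec(algo, seed = 5), d$x, d$y)
    expect_equal(predict_prob(m1, d$x[1:20, ]), predict_prob(m2, d$x[1:20, ]),
                 label = algo)
  }
})

test_that("probabilities are in [0,1] and depth control binds for CART", {
  ch <- small_cohort(3000, seed = 71)
  feats <- build_feature_matrix(ch, c("BPWC_add", "BPWC_mul", "BPWC_dif",
                                      "BMI", "age"))
  for (algo in c("logistic", "cart_tree", "random_forest",
                 "gradient_boosted_trees")) {
    m <- train_model(model_spec(algo, seed = 3), feats, ch$mets)
    p <- predict_prob(m, feats[1:200, ])
    expect_true(all(p >= 0 & p <= 1), label = algo)
  }
  tree <- train_model(model_spec("cart_tree", list(max_depth = 5), seed = 3),
                      feats, ch$mets)
  expect_lte(tree_depth(tree), 5)
  stump <- train_model(model_spec("cart_tree", list(max_depth = 1), seed = 3),
                       feats, ch$mets)
  expect_lte(tree_depth(stump), 1)
})

test_that("logistic regression separates a linearly separable toy exactly", {
  x <- data.frame(a = c(-(5:1), 1:5))
  y <- as.numeric(x$a > 0)
  m <- suppressWarnings(train_model(model_spec("logistic"), x, y))
  expect_equal(as.numeric(predict_prob(m, x) > 0.5), y)
})

test_that("importance ranks a planted signal first across algorithms", {
  for (algo in c("logistic", "cart_tree", "random_forest",
                 "gradient_boosted_trees")) {
    hits <- vapply(1:10, function(s) {
      d <- planted_design(seed = s)
      rk <- suppressWarnings(
        rank_importance(model_spec(algo, seed = s), d$x, d$y))
      rk$feature[1] == "signal"
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("importance ties break lexicographically and singletons rank first", {
  d <- planted_design(n = 300, p_noise = 0)
  # duplicated columns split identically, so CART importances tie exactly
  x <- data.frame(b_copy = d$x$signal, a_copy = d$x$signal)
  rk <- rank_importance(model_spec("cart_tree", seed = 2), x, d$y)
  expect_equal(rk$importance[1], rk$importance[2])
  expect_equal(rk$feature, c("a_copy", "b_copy"))
  rk1 <- rank_importance(model_spec("cart_tree", seed = 2),
                         d$x[, "signal", drop = FALSE], d$y)
  expect_equal(rk1$feature, "signal")
})

test_that("RFE returns a compact set that keeps planted signal", {
  ch <- small_cohort(3000, seed = 81)
  plan <- make_split_plan(ch, reps = 2, seed = 81)
  idx <- plan_indices(plan, ch$id)
  feats <- build_feature_matrix(
    ch, c("BPWC_add", "waist", "BMI", "age", "height", "weight", "hip",
          "carbohydrate_energy", "fat_energy", "grain", "retinol", "kimchi"))
  spec <- model_spec("cart_tree", seed = 81)
  rfe <- rfe_select(spec, feats, ch$mets, idx, max_k = 4)
  expect_lte(length(rfe$features), 4)
  expect_true("BPWC_add" %in% rfe$features)
  # max_k = 1 -> a single feature
  rfe1 <- rfe_select(spec, feats[, c("BPWC_add", "age")], ch$mets, idx,
                     max_k = 1)
  expect_length(rfe1$features, 1)
  expect_error(rfe_select(spec, feats[, 0], ch$mets, idx), "at least one")
})

test_that("ranked-prefix subset search prefers small sufficient sets", {
  ch <- small_cohort(3000, seed = 82)
  plan <- make_split_plan(ch, reps = 2, seed = 82)
  idx <- plan_indices(plan, ch$id)
  feats <- build_feature_matrix(ch, c("BPWC_add", "grain", "retinol",
                                      "kimchi", "lettuce"))
  spec <- model_spec("cart_tree", seed = 82)
  bs <- best_subset(spec, feats, ch$mets, idx)
  expect_true("BPWC_add" %in% bs$features)
  expect_equal(nrow(bs$candidates), 5)
  # single-feature input returns that singleton
  bs1 <- best_subset(spec, feats[, "BPWC_add", drop = FALSE], ch$mets, idx)
  expect_equal(bs1$features, "BPWC_add")
  expect_error(best_subset(spec, feats[, 0], ch$mets, idx), "at least one")
  # exhaustive mode explores 2^k - 1 subsets
  bs3 <- best_subset(spec, feats[, 1:3], ch$mets, idx, exhaustive = TRUE)
  expect_equal(nrow(bs3$candidates), 7)
})

test_that("grid tuning is exhaustive with first-in-grid tie-break", {
  ch <- small_cohort(3000, seed = 83)
  plan <- make_split_plan(ch, reps = 2, seed = 83)
  idx <- plan_indices(plan, ch$id)
  feats <- build_feature_matrix(ch, c("BPWC_add", "BPWC_mul", "BPWC_dif"))
  grid <- desk_grid("cart_tree")
  tuned <- tune_grid("cart_tree", grid, feats, ch$mets, idx, seed = 83)
  expect_true(tuned$best$max_depth %in% c(2, 3, 4, 5))
  expect_equal(length(tuned$scores), length(grid))
  # one-point grid returns that point
  one <- tune_grid("cart_tree", grid[1], feats, ch$mets, idx, seed = 83)
  expect_identical(one$best, grid[[1]])
  # duplicated grid entries tie exactly; the first wins
  two <- tune_grid("cart_tree", c(grid[2], grid[2]), feats, ch$mets, idx,
                   seed = 83)
  expect_equal(two$scores[1], two$scores[2])
  expect_identical(two$best, grid[[2]])
  expect_error(tune_grid("cart_tree", list(), feats, ch$mets, idx), "empty")
})

test_that("three-round selection favours the criterion-scaled features", {
  ch <- small_cohort(3000, seed = 84)
  plan <- make_split_plan(ch, reps = 3, seed = 84)
  idx <- plan_indices(plan, ch$id)
  fams <- feature_families(ch)
  feats <- build_feature_matrix(ch, unique(unlist(fams)))
  spec <- model_spec("cart_tree", seed = 84)
  trace <- run_three_rounds(fams, spec, feats, ch$mets, idx)
  expect_lte(length(trace$final_features), 10)
  expect_true(any(trace$final_features %in% bpwc_family()))
  expect_gt(trace$final_score, 0.7)
  # single-family input degenerates gracefully to one round
  solo <- list(anthropometric = c("BMI", "age"), survey = character(0),
               proposed = character(0))
  expect_warning(tr2 <- run_three_rounds(solo, spec, feats, ch$mets, idx),
                 "empty")
  expect_true(all(tr2$final_features %in% c("BMI", "age")))
})

test_that("all-noise features yield chance-level selection without error", {
  set.seed(85)
  n <- 800
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- sprintf("n%02d", 1:6)
  y <- rbinom(n, 1, 0.3)
  idx <- list(list(train = 1:500, validation = 501:800))
  spec <- model_spec("cart_tree", seed = 85)
  bs <- best_subset(spec, x, y, idx)
  expect_true(bs$score < 0.6)
})
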