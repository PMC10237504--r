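# Train a CART whose single split lands exactly at `threshold` on `var`:
# two tight clusters either side of the cut (rpart splits at their midpoint).
make_boundary_tree <- function(var = "BPWC_add", threshold = 0.66,
                               gap = 0.01, n = 200) {
  lo <- threshold - gap
  hi <- threshold + gap
  x <- data.frame(BPWC_add = rep(1, 2 * n), BPWC_mul = rep(0.2, 2 * n),
                  BPWC_dif = rep(0, 2 * n))
  x[[var]] <- c(rep(lo, n), rep(hi, n))
  # tiny jitter on the other columns so rpart does not see constants
  set.seed(1)
  for (v in setdiff(names(x), var)) x[[v]] <- x[[v]] + runif(2 * n, 0, 1e-6)
  y <- c(rep(0, n), rep(1, n))
  train_model(model_spec("cart_tree", list(max_depth = 1, min_leaf_frac = 0.1,
                                           min_split_frac = 0.2)), x, y)
}

test_that("rule extraction mirrors the tree structure", {
  tree <- make_boundary_tree()
  rules <- extract_rules(tree)
  expect_length(rules, 2)
  expect_equal(vapply(rules, function(r) r$constraints[[1]]$var,
                      character(1)), rep("BPWC_add", 2))
  expect_equal(vapply(rules, function(r) r$constraints[[1]]$threshold,
                      numeric(1)), rep(0.66, 2))
  expect_setequal(vapply(rules, function(r) r$constraints[[1]]$op,
                         character(1)), c("<", ">="))
  expect_equal(sort(vapply(rules, function(r) r$prob, numeric(1))), c(0, 1))

  # a no-split tree yields one unconstrained rule set
  x <- data.frame(BPWC_add = runif(100), BPWC_mul = runif(100),
                  BPWC_dif = runif(100) - 0.5)
  stump <- train_model(model_spec("cart_tree", list(cp = 1)),
                       x, rbinom(100, 1, 0.5))
  r0 <- extract_rules(stump)
  expect_length(r0, 1)
  expect_length(r0[[1]]$constraints, 0)

  # depth-5 tree has at most 2^5 leaves
  ch <- small_cohort(3000, seed = 91)
  fit <- fit_bpwc_tree(ch, seed = 91)
  expect_lte(length(extract_rules(fit$model)), 32)

  # trees over non-mappable features are refused by name
  bad <- train_model(model_spec("cart_tree"),
                     build_feature_matrix(ch, c("waist", "age")), ch$mets)
  expect_error(extract_rules(bad), "waist")
})

test_that("constraints map to the documented curves and detect emptiness", {
  tree <- make_boundary_tree()
  rules <- extract_rules(tree)
  below <- rules[[which(vapply(rules, function(r) r$constraints[[1]]$op,
                               character(1)) == "<")]]
  pl <- rules_to_plane(below)
  expect_false(pl$empty)
  expect_true(pl$contains(0.1, 0.1))   # BP + WC = 0.2 < 0.66
  expect_false(pl$contains(0.5, 0.5))  # 1.0 >= 0.66
  expect_match(pl$boundaries, "line BP = 0.66 - WC")

  contradiction <- list(leaf = 99L, constraints = list(
    list(var = "BPWC_add", op = "<", threshold = 0.4),
    list(var = "BPWC_add", op = ">=", threshold = 0.6)),
    n_pos = 0, n_neg = 0, prob = 0)
  expect_true(rules_to_plane(contradiction)$empty)

  mul_rule <- list(leaf = 1L, constraints = list(
    list(var = "BPWC_mul", op = ">=", threshold = 0.31)),
    n_pos = 1, n_neg = 0, prob = 1)
  pm <- rules_to_plane(mul_rule)
  expect_true(pm$contains(0.66, 0.8448))  # 0.5576 above the hyperbola
  expect_false(pm$contains(0.3, 0.3))
  expect_match(pm$boundaries, "hyperbola")
})

test_that("risk map carries calibrated risk ratios, zones and PPV bands", {
  tree <- make_boundary_tree()
  map <- build_risk_map(tree, threshold = 0.137,
                        calibrated_leaf_probs = NULL, beta = 0.16)
  expect_length(map$regions, 2)
  safety <- map$regions[[which(vapply(map$regions, function(r) !r$class,
                                      logical(1)))]]
  expect_equal(safety$zone, "safety") # whole region under BP + WC = 0.66
  expect_equal(safety$ppv_zone, "green")

  # override with explicit calibrated probabilities: worked risk ratio
  rules <- extract_rules(tree)
  leaves <- as.character(vapply(rules, function(r) r$leaf, numeric(1)))
  probs <- stats::setNames(c(0.31, 0.137), leaves)
  map2 <- build_risk_map(tree, threshold = 0.137,
                         calibrated_leaf_probs = probs)
  risks <- vapply(map2$regions, function(r) r$risk, numeric(1))
  expect_equal(sort(risks), sort(c(0.31 / 0.137, 1)))
  expect_equal(round(max(risks), 2), 2.26)
  zones <- vapply(map2$regions, function(r) r$ppv_zone, character(1))
  expect_setequal(zones, c("yellow", "green")) # risk 2.26 -> yellow, 1 -> green
  # a leaf at calibrated p == threshold has risk exactly 1
  expect_equal(min(risks), 1)
  # missing leaf probability is an error
  expect_error(build_risk_map(tree, 0.137,
                              calibrated_leaf_probs = probs[1]), "missing")

  # region entirely above the BP*WC = 0.31 hyperbola is a risk zone
  mtree <- make_boundary_tree(var = "BPWC_mul", threshold = 0.31)
  mmap <- build_risk_map(mtree, threshold = 0.137, beta = 0.16)
  upper <- mmap$regions[[which(vapply(mmap$regions, function(r) {
    r$constraints[[1]]$op == ">="
  }, logical(1)))]]
  expect_equal(upper$zone, "risk")
})

test_that("locate resolves points to the unique containing region", {
  tree <- make_boundary_tree()
  map <- build_risk_map(tree, threshold = 0.137, beta = 0.16)
  expect_equal(locate(map, 0.1, 0.1)$zone, "safety")
  mtree <- make_boundary_tree(var = "BPWC_mul", threshold = 0.31)
  mmap <- build_risk_map(mtree, threshold = 0.137, beta = 0.16)
  expect_equal(locate(mmap, 0.66, 0.8448)$zone, "risk")
  expect_error(locate(map, 1.2, 0.5), "unit square")
})

test_that("regions partition the unit square", {
  ch <- small_cohort(3000, seed = 92)
  fit <- fit_bpwc_tree(ch, seed = 92)
  map <- build_risk_map(fit$model, threshold = 0.136, beta = 0.157)
  g <- seq(0.0005, 0.9995, length.out = 500)
  pts <- expand.grid(wc = g, bp = g)
  cover <- rep(0L, nrow(pts))
  for (r in map$regions) {
    cover <- cover + rules_to_plane(r)$contains(pts$wc, pts$bp)
  }
  expect_true(all(cover == 1L))
})

test_that("risk is monotone along the diagonal for a monotone signal", {
  set.seed(93)
  n <- 4000
  add <- runif(n, 0, 2)
  x <- data.frame(BPWC_add = add)
  y <- rbinom(n, 1, plogis(8 * (add - 1)))
  tree <- train_model(model_spec("cart_tree", list(max_depth = 3)), x, y)
  map <- build_risk_map(tree, threshold = 0.5, beta = 1)
  risks <- vapply(seq(0.05, 0.95, 0.05), function(t) locate(map, t, t)$risk,
                  numeric(1))
  expect_true(all(diff(risks) >= 0))
})

test_that("raw-value axis ticks invert the scaling", {
  expect_equal(raw_axis_ticks("WC-female", 0.5)$raw, 85)
  expect_equal(raw_axis_ticks("WC-male", 0.5)$raw, 90)
  # a systolic reading of 131 mmHg sits at tick 0.6 after one-decimal rounding
  t06 <- raw_axis_ticks("BP-systolic", 0.6)$raw
  expect_equal(t06, 131.125)
  expect_equal(round(elliot_scale(131, spec_sbp()), 1), 0.6)
  ticks <- seq(0.05, 0.95, 0.05)
  for (ax in c("WC-male", "WC-female", "BP-systolic", "BP-diastolic")) {
    tab <- raw_axis_ticks(ax, ticks)
    sp <- switch(ax, "WC-male" = spec_wc("M"), "WC-female" = spec_wc("F"),
                 "BP-systolic" = spec_sbp(), "BP-diastolic" = spec_dbp())
    expect_lt(max(abs(elliot_scale(tab$raw, sp) - ticks)), 1e-9)
  }
  expect_error(raw_axis_ticks("BP-systolic", 1.5), "\\(0, 1\\)")
})

test_that("maps export to JSON and import back identically", {
  ch <- small_cohort(3000, seed = 94)
  fit <- fit_bpwc_tree(ch, seed = 94)
  map <- build_risk_map(fit$model, threshold = 0.136, beta = 0.157)
  p <- tempfile(fileext = ".json")
  export_map(map, p)
  back <- import_map(p)
  expect_equal(length(back$regions), length(map$regions))
  expect_equal(back$threshold, map$threshold)
  for (i in seq_along(map$regions)) {
    expect_equal(back$regions[[i]]$constraints, map$regions[[i]]$constraints)
    expect_equal(back$regions[[i]]$risk, map$regions[[i]]$risk)
    expect_equal(back$regions[[i]]$zone, map$regions[[i]]$zone)
  }
  # exported document schema-checks: parses with the expected top-level keys
  doc <- jsonlite::read_json(p)
  expect_true(all(c("schema", "threshold", "regions", "axis_ticks") %in%
                    names(doc)))
  unlink(p)

  # a single-leaf map covers the square with one region
  x <- data.frame(BPWC_add = runif(100), BPWC_mul = runif(100),
                  BPWC_dif = runif(100) - 0.5)
  stump <- train_model(model_spec("cart_tree", list(cp = 1)),
                       x, rbinom(100, 1, 0.5))
  m0 <- build_risk_map(stump, threshold = 0.5, beta = 1)
  expect_length(m0$regions, 1)
  expect_equal(locate(m0, 0.9, 0.9)$leaf, m0$regions[[1]]$leaf)
})
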