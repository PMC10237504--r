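# Features that are deterministic functions of (WC, BP), hence drawable in
# the unit square: lines for add/dif, hyperbolas for mul/con, axis-parallel
# lines for the two axes themselves.
#' Features expressible in the (WC, BP) plane
#'
#' @return character vector of feature names a risk map can be built from.
#' @export
mappable_features <- function() c("BPWC_add", "BPWC_mul", "BPWC_dif",
                                  "BPWC_con", "WC", "BP")

# Evaluate a mappable feature at (wc, bp).
plane_value <- function(var, wc, bp) {
  switch(var,
    BPWC_add = bp + wc,
    BPWC_mul = bp * wc,
    BPWC_dif = bp - wc,
    BPWC_con = pmax(bp * wc - 0.25, 0),
    WC = wc,
    BP = bp,
    stop(sprintf("feature '%s' is not expressible in the (WC, BP) plane",
                 var))
  )
}

#' Extract leaf rule sets from a fitted CART model
#'
#' One rule set per terminal node: the conjunction of the root-to-leaf split
#' conditions, using the tree's own boundary convention (a `<` condition
#' sends a record left). Each rule set carries the leaf's training class
#' counts and its uncalibrated positive probability. Trees using a feature
#' that is not expressible in the (WC, BP) plane raise an error naming it.
#'
#' @param model a `trained_model` with algorithm "cart_tree".
#' @return list of rule sets: `leaf` (node number), `constraints` (list of
#'   `var`/`op`/`threshold`), `n_pos`, `n_neg`, `prob`.
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "trained_model"),
            model$spec$algorithm == "cart_tree")
  fit <- model$fit
  frame <- fit$frame
  used <- setdiff(unique(as.character(frame$var)), "<leaf>")
  bad <- setdiff(used, mappable_features())
  if (length(bad) > 0) {
    stop(sprintf("tree splits on non-mappable feature(s): %s",
                 paste(bad, collapse = ", ")))
  }
  nodes <- as.integer(rownames(frame))
  # primary split per internal node: first of its block in fit$splits
  internal <- which(frame$var != "<leaf>")
  split_row <- integer(nrow(frame))
  pos <- 1L
  for (i in seq_len(nrow(frame))) {
    if (frame$var[i] != "<leaf>") {
      split_row[i] <- pos
      pos <- pos + 1L + frame$ncompete[i] + frame$nsurrogate[i]
    }
  }
  node_split <- function(i) {
    s <- fit$splits[split_row[i], , drop = FALSE]
    list(var = as.character(frame$var[i]),
         threshold = unname(s[, "index"]),
         left_op = if (s[, "ncat"] < 0) "<" else ">=")
  }
  flip <- c("<" = ">=", ">=" = "<")
  rulesets <- list()
  walk <- function(node, constraints) {
    i <- match(node, nodes)
    if (frame$var[i] == "<leaf>") {
      yv <- frame$yval2[i, , drop = TRUE]
      n0 <- unname(yv[2]); n1 <- unname(yv[3])
      rulesets[[length(rulesets) + 1]] <<- list(
        leaf = node, constraints = constraints,
        n_pos = n1, n_neg = n0, prob = n1 / (n0 + n1))
      return(invisible(NULL))
    }
    sp <- node_split(i)
    walk(2L * node, c(constraints, list(list(
      var = sp$var, op = sp$left_op, threshold = sp$threshold))))
    walk(2L * node + 1L, c(constraints, list(list(
      var = sp$var, op = unname(flip[sp$left_op]),
      threshold = sp$threshold))))
  }
  walk(1L, list())
  rulesets
}

# TRUE where (wc, bp) satisfies every constraint of a rule set.
ruleset_contains <- function(ruleset, wc, bp) {
  ok <- rep(TRUE, length(wc))
  for (cn in ruleset$constraints) {
    v <- plane_value(cn$var, wc, bp)
    ok <- ok & if (cn$op == "<") v < cn$threshold else v >= cn$threshold
  }
  ok
}

#' Plane-region descriptor of a rule set
#'
#' Maps each constraint to its boundary curve in the (WC, BP) unit square
#' (`BPWC_add = c` and `BPWC_dif = c` are lines of slope -1 / +1,
#' `BPWC_mul = c` the hyperbola `BP = c / WC`) and tests emptiness of the
#' intersection numerically on a grid.
#'
#' @param ruleset one element of [extract_rules()].
#' @param grid_n grid resolution per axis for the emptiness check.
#' @return list with the `constraints`, a `contains(wc, bp)` predicate,
#'   `boundaries` (human-readable curve descriptions) and `empty` flag.
#' @export
rules_to_plane <- function(ruleset, grid_n = 201) {
  g <- seq(0, 1, length.out = grid_n + 2)[2:(grid_n + 1)]
  pts <- expand.grid(wc = g, bp = g)
  inside <- ruleset_contains(ruleset, pts$wc, pts$bp)
  boundaries <- vapply(ruleset$constraints, function(cn) {
    curve <- switch(cn$var,
      BPWC_add = sprintf("line BP = %.4g - WC", cn$threshold),
      BPWC_dif = sprintf("line BP = %.4g + WC", cn$threshold),
      BPWC_mul = sprintf("hyperbola BP = %.4g / WC", cn$threshold),
      BPWC_con = sprintf("hyperbola BP = %.4g / WC", cn$threshold + 0.25),
      WC = sprintf("vertical line WC = %.4g", cn$threshold),
      BP = sprintf("horizontal line BP = %.4g", cn$threshold))
    sprintf("%s %s %.6g (%s)", cn$var, cn$op, cn$threshold, curve)
  }, character(1))
  list(constraints = ruleset$constraints,
       contains = function(wc, bp) ruleset_contains(ruleset, wc, bp),
       boundaries = boundaries,
       empty = !any(inside))
}

#' Build a calibrated MetS risk map from a CART model
#'
#' Converts each terminal node into a region of the (WC, BP) unit square.
#' Each region carries a calibrated probability (by default the
#' undersampling-corrected leaf probability), a risk ratio
#' `risk = calibrated p / threshold` (risk >= 1 classifies the region as
#' MetS), a prevention zone and a PPV band. Zones: `safety` where the whole
#' region satisfies `BP + WC <= zone_add`, `risk` where it satisfies
#' `BP * WC >= zone_mul`, otherwise `warning` (decided numerically on the
#' grid). PPV bands: green `risk <= 1`, red `risk >= 4`, yellow in between.
#' Empty regions (unsatisfiable conjunctions) are dropped with a message.
#'
#' @param model a CART `trained_model` over mappable features.
#' @param threshold decision threshold, see [pozzolo_threshold()].
#' @param beta negative-retention probability of the undersampled training
#'   set, used to correct the leaf probabilities.
#' @param calibrated_leaf_probs optional named vector (by leaf node number)
#'   overriding the corrected leaf probabilities.
#' @param zone_add,zone_mul zone boundary levels (defaults 0.66 and 0.31,
#'   the fitted boundaries of the study map; they derive from the specific
#'   tree at hand, so they are configuration, not constants).
#' @param grid_n grid resolution for zone assignment and emptiness checks.
#' @return a `risk_map` object.
#' @export
build_risk_map <- function(model, threshold, beta = NULL,
                           calibrated_leaf_probs = NULL,
                           zone_add = 0.66, zone_mul = 0.31, grid_n = 201) {
  rulesets <- extract_rules(model)
  leaves <- vapply(rulesets, function(r) r$leaf, numeric(1))
  if (is.null(calibrated_leaf_probs)) {
    if (is.null(beta)) stop("either beta or calibrated_leaf_probs is required")
    calibrated_leaf_probs <- stats::setNames(
      pozzolo_correct(vapply(rulesets, function(r) r$prob, numeric(1)), beta),
      as.character(leaves))
  }
  miss <- setdiff(as.character(leaves), names(calibrated_leaf_probs))
  if (length(miss) > 0) {
    stop(sprintf("missing calibrated probability for leaf node(s): %s",
                 paste(miss, collapse = ", ")))
  }
  g <- seq(0, 1, length.out = grid_n + 2)[2:(grid_n + 1)]
  pts <- expand.grid(wc = g, bp = g)
  regions <- list()
  for (r in rulesets) {
    inside <- ruleset_contains(r, pts$wc, pts$bp)
    if (!any(inside)) {
      message(sprintf("leaf %d yields an empty region; dropped", r$leaf))
      next
    }
    p_cal <- unname(calibrated_leaf_probs[as.character(r$leaf)])
    risk <- p_cal / threshold
    addv <- pts$bp[inside] + pts$wc[inside]
    mulv <- pts$bp[inside] * pts$wc[inside]
    zone <- if (all(addv <= zone_add)) "safety"
            else if (all(mulv >= zone_mul)) "risk"
            else "warning"
    ppv_zone <- if (risk <= 1) "green" else if (risk >= 4) "red" else "yellow"
    regions[[length(regions) + 1]] <- list(
      leaf = r$leaf, constraints = r$constraints,
      n_pos = r$n_pos, n_neg = r$n_neg, uncalibrated_prob = r$prob,
      calibrated_prob = p_cal, risk = risk, class = risk >= 1,
      zone = zone, ppv_zone = ppv_zone)
  }
  structure(list(regions = regions, threshold = threshold,
                 zone_add = zone_add, zone_mul = zone_mul),
            class = "risk_map")
}

#' Locate a point on the risk map
#'
#' @param map a `risk_map`.
#' @param wc,bp scaled coordinates, strictly inside (0, 1). Boundary points
#'   resolve by the tree's own split convention (`<` goes left), so the
#'   located region always agrees with the tree's prediction.
#' @return the matching region (a list; see [build_risk_map()]).
#' @export
locate <- function(map, wc, bp) {
  if (wc <= 0 || wc >= 1 || bp <= 0 || bp >= 1) {
    stop("point must lie strictly inside the unit square")
  }
  for (r in map$regions) {
    if (ruleset_contains(r, wc, bp)) return(r)
  }
  stop("no region contains the point (dropped empty region?)")
}

#' Raw-value axis ticks
#'
#' Maps scaled tick positions back to raw measurements through the inverse
#' elliot scaling, for annotating the map axes in cm / mmHg.
#'
#' @param axis one of "WC-male", "WC-female", "BP-systolic", "BP-diastolic".
#' @param ticks scaled positions in (0, 1).
#' @return data frame with `scaled` and `raw` columns.
#' @export
raw_axis_ticks <- function(axis, ticks) {
  if (any(ticks <= 0 | ticks >= 1)) stop("ticks must lie in (0, 1)")
  spec <- switch(axis,
    "WC-male" = spec_wc("M"),
    "WC-female" = spec_wc("F"),
    "BP-systolic" = spec_sbp(),
    "BP-diastolic" = spec_dbp(),
    stop(sprintf("unknown axis '%s'", axis)))
  data.frame(scaled = ticks, raw = inverse_elliot(ticks, spec))
}

#' Export / import a risk map as JSON
#'
#' The JSON document lists the regions (constraints, probabilities, risk,
#' zones), the threshold and zone boundaries, and raw-value tick tables for
#' the four axis variants.
#'
#' @param map a `risk_map`.
#' @param path file path.
#' @export
export_map <- function(map, path) {
  ticks <- seq(0.1, 0.9, by = 0.1)
  doc <- list(
    schema = "metsrisk/risk_map/v1",
    threshold = map$threshold,
    zone_add = map$zone_add, zone_mul = map$zone_mul,
    regions = lapply(map$regions, function(r) {
      r$constraints <- lapply(r$constraints, function(cn) {
        list(var = cn$var, op = cn$op, threshold = cn$threshold)
      })
      r
    }),
    axis_ticks = lapply(stats::setNames(nm = c("WC-male", "WC-female",
                                               "BP-systolic",
                                               "BP-diastolic")),
                        function(a) raw_axis_ticks(a, ticks))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_map
#' @export
import_map <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- lapply(doc$regions, function(r) {
    r$constraints <- lapply(r$constraints, function(cn) {
      list(var = cn$var, op = cn$op, threshold = as.numeric(cn$threshold))
    })
    r$class <- isTRUE(r$class)
    for (f in c("n_pos", "n_neg", "uncalibrated_prob", "calibrated_prob",
                "risk", "leaf")) {
      r[[f]] <- as.numeric(r[[f]])
    }
    r
  })
  structure(list(regions = regions, threshold = as.numeric(doc$threshold),
                 zone_add = as.numeric(doc$zone_add),
                 zone_mul = as.numeric(doc$zone_mul)),
            class = "risk_map")
}

#' Rasterised risk-map figure
#'
#' Renders the region partition as a raster over the unit square, coloured by
#' risk ratio, with the two zone boundary curves. Requires ggplot2.
#'
#' @param map a `risk_map`.
#' @param resolution raster resolution per axis.
#' @return a ggplot object.
#' @export
plot_risk_map <- function(map, resolution = 300) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_risk_map requires the ggplot2 package")
  }
  g <- seq(0, 1, length.out = resolution + 2)[2:(resolution + 1)]
  pts <- expand.grid(WC = g, BP = g)
  pts$risk <- NA_real_
  for (r in map$regions) {
    idx <- is.na(pts$risk) & ruleset_contains(r, pts$WC, pts$BP)
    pts$risk[idx] <- r$risk
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = WC, y = BP, fill = risk)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2c7fb8", mid = "#ffffcc",
                                  high = "#d7301f", midpoint = 1,
                                  name = "risk ratio") +
    ggplot2::geom_function(fun = function(x) map$zone_add - x,
                           colour = "red") +
    ggplot2::geom_function(fun = function(x) map$zone_mul / x,
                           colour = "darkred", linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "WC (scaled waist)", y = "BP (scaled blood pressure)")
}
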