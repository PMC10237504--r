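#' Model specification
#'
#' @param algorithm one of "logistic", "cart_tree", "random_forest",
#'   "gradient_boosted_trees".
#' @param hyperparameters named list; unknown names raise an error. Defaults:
#'   * cart_tree: `max_depth` 5, `criterion` "gini", `min_split_frac` 0.01,
#'     `min_leaf_frac` 0.013 (a 200-record leaf floor rescaled as a fraction
#'     of a ~15,600-record training set so the constraint transfers to
#'     smaller cohorts), `cp` 0.
#'   * logistic: `standardize` TRUE.
#'   * random_forest: `num_trees` 300, `max_depth` 0 (unlimited),
#'     `min_node_size` 10.
#'   * gradient_boosted_trees: `nrounds` 150, `max_depth` 4, `eta` 0.1,
#'     `subsample` 0.8.
#' @param seed integer seed used for every stochastic fit.
#' @return a `model_spec` object.
#' @export
model_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algos <- c("logistic", "cart_tree", "random_forest",
             "gradient_boosted_trees")
  if (!algorithm %in% algos) {
    stop(sprintf("unknown algorithm '%s'; must be one of %s", algorithm,
                 paste(algos, collapse = ", ")))
  }
  defaults <- switch(algorithm,
    logistic = list(standardize = TRUE),
    cart_tree = list(max_depth = 5, criterion = "gini",
                     min_split_frac = 0.01, min_leaf_frac = 200 / 15560,
                     cp = 0),
    random_forest = list(num_trees = 300, max_depth = 0, min_node_size = 10),
    gradient_boosted_trees = list(nrounds = 150, max_depth = 4, eta = 0.1,
                                  subsample = 0.8)
  )
  bad <- setdiff(names(hyperparameters), names(defaults))
  if (length(bad) > 0) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", algorithm,
                 paste(bad, collapse = ", ")))
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  if (algorithm == "cart_tree" && !hp$criterion %in% c("gini", "entropy")) {
    stop("cart_tree criterion must be 'gini' or 'entropy'")
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)), class = "model_spec")
}

#' Train a classifier
#'
#' Thin, seed-deterministic wrapper over the standard learners: [stats::glm()]
#' (logistic), [rpart::rpart()] (CART), [ranger::ranger()] (random forest) and
#' [xgboost::xgboost()] (gradient-boosted trees). All expose class-probability
#' prediction through [predict_prob()].
#'
#' @param spec a [model_spec()].
#' @param features numeric feature data frame (no missing values).
#' @param labels binary labels, both classes present.
#' @return a `trained_model` object.
#' @export
train_model <- function(spec, features, labels) {
  stopifnot(inherits(spec, "model_spec"))
  if (ncol(features) == 0) stop("cannot train on an empty feature matrix")
  if (anyNA(features)) stop("features contain missing values")
  y <- as.integer(as.logical(labels))
  if (all(y == 0) || all(y == 1)) {
    stop("training labels are single-class")
  }
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  n <- nrow(features)
  fit <- switch(spec$algorithm,
    logistic = {
      ctr <- NULL
      x <- features
      if (isTRUE(hp$standardize)) {
        mu <- vapply(x, mean, numeric(1))
        sdv <- vapply(x, stats::sd, numeric(1))
        sdv[sdv == 0] <- 1
        x <- as.data.frame(scale(x, center = mu, scale = sdv))
        ctr <- list(center = mu, scale = sdv)
      }
      d <- cbind(x, .y = y)
      m <- stats::glm(.y ~ ., data = d, family = stats::binomial())
      list(fit = m, scaler = ctr)
    },
    cart_tree = {
      d <- cbind(features, .y = factor(y, levels = c(0, 1)))
      rpart::rpart(
        .y ~ ., data = d, method = "class",
        parms = list(split = if (hp$criterion == "gini") "gini"
                     else "information"),
        control = rpart::rpart.control(
          maxdepth = hp$max_depth,
          minsplit = max(2L, ceiling(hp$min_split_frac * n)),
          minbucket = max(1L, ceiling(hp$min_leaf_frac * n)),
          cp = hp$cp, xval = 0))
    },
    random_forest = {
      d <- cbind(features, .y = factor(y, levels = c(0, 1)))
      ranger::ranger(.y ~ ., data = d, probability = TRUE,
                     num.trees = hp$num_trees,
                     max.depth = hp$max_depth,
                     min.node.size = hp$min_node_size,
                     importance = "impurity", seed = spec$seed,
                     num.threads = 1)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = y,
                                     nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      subsample = hp$subsample, nthread = 1,
                      seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    }
  )
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(features)),
            class = "trained_model")
}

#' Class-probability prediction
#'
#' @param model a `trained_model`.
#' @param features data frame containing at least the training features.
#' @return vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, features) {
  features <- features[, model$feature_names, drop = FALSE]
  switch(model$spec$algorithm,
    logistic = {
      x <- features
      sc <- model$fit$scaler
      if (!is.null(sc)) {
        x <- as.data.frame(scale(x, center = sc$center, scale = sc$scale))
      }
      unname(stats::predict(model$fit$fit, newdata = x, type = "response"))
    },
    cart_tree = unname(stats::predict(model$fit, newdata = features)[, "1"]),
    random_forest =
      unname(stats::predict(model$fit, data = features,
                            num.threads = 1)$predictions[, "1"]),
    gradient_boosted_trees =
      unname(stats::predict(model$fit,
                            xgboost::xgb.DMatrix(as.matrix(features),
                                                 nthread = 1)))
  )
}

#' Tree depth of a fitted CART model
#'
#' @param model a `trained_model` with algorithm "cart_tree".
#' @return integer depth (0 for a stump with no split).
#' @export
tree_depth <- function(model) {
  stopifnot(model$spec$algorithm == "cart_tree")
  nodes <- as.integer(rownames(model$fit$frame))
  max(floor(log2(nodes)))
}

#' Algorithm-native feature importance
#'
#' Tree families report impurity-based importance; logistic regression
#' reports `exp(|coefficient|)` on standardised inputs. Features unused by a
#' fit get importance 0. Ties are broken lexicographically by feature name,
#' so ranking is deterministic.
#'
#' @param spec a [model_spec()].
#' @param features feature data frame.
#' @param labels binary labels.
#' @return data frame with `feature` and `importance`, in rank order.
#' @export
rank_importance <- function(spec, features, labels) {
  model <- train_model(spec, features, labels)
  imp_of <- importance_values(model)
  imp <- imp_of[colnames(features)]
  imp[is.na(imp)] <- 0
  names(imp) <- colnames(features)
  o <- order(-imp, names(imp))
  data.frame(feature = names(imp)[o], importance = unname(imp[o]),
             stringsAsFactors = FALSE)
}

importance_values <- function(model) {
  switch(model$spec$algorithm,
    logistic = {
      co <- stats::coef(model$fit$fit)[-1]
      nm <- model$feature_names
      # glm mangles non-syntactic names; map positionally
      out <- exp(abs(unname(co)))
      names(out) <- nm
      out
    },
    cart_tree = {
      vi <- model$fit$variable.importance
      if (is.null(vi)) vi <- stats::setNames(numeric(0), character(0))
      vi
    },
    random_forest = ranger::importance(model$fit),
    gradient_boosted_trees = {
      it <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(it$Gain, it$Feature)
    }
  )
}
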