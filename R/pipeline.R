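#' Pipeline configuration
#'
#' @param n synthetic cohort size (ignored when `cohort_path` is given).
#' @param prevalence target MetS prevalence of the synthetic cohort.
#' @param seed master seed for every stage.
#' @param cohort_path optional CSV of an existing cohort (columns as in
#'   [write_cohort()]); when `NULL` a synthetic cohort is generated.
#' @param algorithms classifier families to run.
#' @param reps repetitions of the train/validation re-split (default 30).
#' @param selection_reps,tuning_reps how many repetitions feature selection /
#'   grid search average over (desk-scale defaults 3 and 5).
#' @param feature_names optional fixed feature set per algorithm (named list);
#'   when given, the three-round selection is skipped for that algorithm.
#' @param grids optional named list of hyperparameter grids; defaults to
#'   [desk_grid()] per algorithm.
#' @param calibration_methods methods compared by [select_calibration()].
#' @param test_frac,val_frac split fractions (defaults 0.1 / 0.1).
#' @param top_m,max_k selection filter sizes.
#' @param out_dir optional artifact directory.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(n = 20000, prevalence = 0.136, seed = 1L,
                            cohort_path = NULL,
                            algorithms = c("cart_tree", "logistic"),
                            reps = 30, selection_reps = 3, tuning_reps = 5,
                            feature_names = NULL, grids = NULL,
                            calibration_methods = c("platt", "isotonic",
                                                    "pozzolo"),
                            test_frac = 0.1, val_frac = 0.1,
                            top_m = 30, max_k = 10, out_dir = NULL) {
  known <- c("logistic", "cart_tree", "random_forest",
             "gradient_boosted_trees")
  bad <- setdiff(algorithms, known)
  if (length(bad) > 0) {
    stop(sprintf("unknown algorithm(s) in config: %s",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop(sprintf("cohort_path '%s' does not exist", cohort_path))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[order(names(unclass(config)))], tmp,
                       auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end experiment
#'
#' Stages: cohort (generate or load, then diagnose), feature assembly,
#' split plan, per-algorithm three-round feature selection, grid tuning,
#' final fit on the first repetition's undersampled training fold,
#' calibration-method comparison fitted on that repetition's validation fold,
#' test-set evaluation at the undersampling-corrected threshold, and — for a
#' CART model over plane-mappable features — the calibrated risk map.
#' Artifacts are stamped with the seed and a config hash.
#'
#' @param config a [pipeline_config()].
#' @return list with `cohort_summary`, `plan`, per-algorithm `models`
#'   (selection trace, tuned parameters, calibration, test metrics),
#'   `report` (comparison table), `risk_map` (or NULL) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(s) message(sprintf("[pipeline] %s", s))
  run_stage <- function(s, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", s, conditionMessage(e)),
           call. = FALSE)
    })
  }

  stage("cohort")
  cohort <- run_stage("cohort", {
    if (is.null(config$cohort_path)) {
      generate_cohort(cohort_spec(config$n, config$prevalence,
                                  seed = config$seed))
    } else {
      filter_eligible(read_cohort(config$cohort_path))
    }
  })
  cohort <- label_cohort(cohort)

  stage("features")
  fams <- feature_families(cohort)
  all_names <- unique(unlist(fams, use.names = FALSE))
  features <- run_stage("features", build_feature_matrix(cohort, all_names))
  labels <- cohort$mets

  stage("split plan")
  plan <- run_stage("split plan",
                    make_split_plan(cohort, config$test_frac, config$val_frac,
                                    config$reps, config$seed))
  splits_all <- plan_indices(plan, cohort$id)
  test_idx <- attr(splits_all, "test")
  pool_idx <- attr(splits_all, "pool")
  threshold <- pozzolo_threshold(labels[pool_idx])

  models <- list()
  risk_map <- NULL
  for (algo in config$algorithms) {
    stage(sprintf("model %s: feature selection", algo))
    sel_splits <- splits_all[seq_len(min(config$selection_reps,
                                         length(splits_all)))]
    base_spec <- model_spec(algo, seed = config$seed)
    fixed <- config$feature_names[[algo]]
    trace <- NULL
    feats <- if (!is.null(fixed)) fixed else {
      trace <- run_stage("selection",
                         run_three_rounds(fams, base_spec, features, labels,
                                          sel_splits, config$top_m,
                                          config$max_k))
      trace$final_features
    }

    stage(sprintf("model %s: tuning", algo))
    tune_splits <- splits_all[seq_len(min(config$tuning_reps,
                                          length(splits_all)))]
    grid <- config$grids[[algo]] %||% desk_grid(algo)
    tuned <- run_stage("tuning",
                       tune_grid(algo, grid,
                                 features[, feats, drop = FALSE], labels,
                                 tune_splits, seed = config$seed))
    spec <- model_spec(algo, tuned$best, seed = config$seed)

    stage(sprintf("model %s: final fit + calibration", algo))
    rep1 <- splits_all[[1]]
    model <- run_stage("final fit",
                       train_model(spec,
                                   features[rep1$train, feats, drop = FALSE],
                                   labels[rep1$train]))
    # beta: fraction of the repetition's negatives kept by the undersample
    train_pool_idx <- setdiff(pool_idx, rep1$validation)
    n_pos_tr <- sum(labels[train_pool_idx] == 1)
    n_neg_tr <- sum(labels[train_pool_idx] == 0)
    beta <- n_pos_tr / n_neg_tr
    cal <- run_stage("calibration", select_calibration(
      model,
      features[rep1$validation, feats, drop = FALSE],
      labels[rep1$validation],
      features[test_idx, feats, drop = FALSE], labels[test_idx],
      beta = beta, methods = config$calibration_methods))

    stage(sprintf("model %s: test evaluation", algo))
    test_scores <- cal$calibrators[[cal$best]](
      predict_prob(model, features[test_idx, feats, drop = FALSE]))
    panel <- run_stage("evaluation",
                       metric_panel(test_scores, labels[test_idx], threshold))

    models[[algo]] <- list(
      algorithm = algo, features = feats, trace = trace,
      tuned = tuned$best, tuned_score = tuned$best_score,
      model = model, beta = beta, threshold = threshold,
      calibration = cal, metrics = panel)

    if (algo == "cart_tree") {
      # the map needs a tree over plane-expressible features; refit on the
      # mappable subset of the selected set when others were selected
      map_feats <- intersect(feats, mappable_features())
      if (length(map_feats) == 0) {
        message("risk map skipped: no plane-expressible feature selected")
      } else {
        stage("risk map")
        map_model <- if (setequal(map_feats, feats)) model else
          run_stage("risk map fit",
                    train_model(spec,
                                features[rep1$train, map_feats,
                                         drop = FALSE],
                                labels[rep1$train]))
        risk_map <- run_stage("risk map",
                              build_risk_map(map_model, threshold,
                                             beta = beta))
        models[[algo]]$risk_map_features <- map_feats
      }
    }
  }

  report <- final_model_report(models)
  provenance <- list(seed = config$seed, config_hash = config_hash(config),
                     package_version =
                       as.character(utils::packageVersion("metsrisk")),
                     elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    write_split_plan(plan, file.path(config$out_dir, "plan.json"))
    utils::write.csv(report, file.path(config$out_dir, "model_report.csv"),
                     row.names = FALSE)
    for (algo in names(models)) {
      m <- models[[algo]]
      jsonlite::write_json(
        list(provenance = provenance, algorithm = algo,
             features = m$features, tuned = m$tuned,
             threshold = m$threshold, beta = m$beta,
             best_calibration = m$calibration$best,
             calibration_reports = lapply(m$calibration$reports, function(r) {
               list(method = r$method, brier = r$brier,
                    spiegelhalter_z = r$spiegelhalter_z,
                    spiegelhalter_p = r$spiegelhalter_p, curve = r$curve)
             }),
             metrics = m$metrics),
        file.path(config$out_dir, sprintf("model_%s.json", algo)),
        auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (!is.null(risk_map)) {
      export_map(risk_map, file.path(config$out_dir, "risk_map.json"))
    }
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }

  list(cohort_summary = cohort_summary(cohort), plan = plan, models = models,
       report = report, risk_map = risk_map, provenance = provenance)
}

#' Model comparison table
#'
#' One row per evaluated model: test discrimination metrics, feature counts
#' (synthetic features expanded to their distinct raw measurements), the
#' selected calibration method with its goodness statistics, and an
#' interpretability note.
#'
#' @param models per-algorithm results from [run_pipeline()] (possibly
#'   empty).
#' @return data frame.
#' @export
final_model_report <- function(models) {
  if (length(models) == 0) {
    return(data.frame(algorithm = character(0)))
  }
  interp <- c(logistic = "easy", cart_tree = "easy",
              random_forest = "hard", gradient_boosted_trees = "hard")
  do.call(rbind, lapply(models, function(m) {
    best <- m$calibration$reports[[m$calibration$best]]
    data.frame(
      algorithm = m$algorithm,
      auc = m$metrics$auc, recall = m$metrics$recall,
      specificity = m$metrics$specificity, bacc = m$metrics$bacc,
      n_features = length(m$features),
      n_raw_features = raw_feature_count(m$features),
      calibration = m$calibration$best,
      brier = best$brier, spiegelhalter_z = best$spiegelhalter_z,
      spiegelhalter_p = best$spiegelhalter_p,
      interpretability = unname(interp[m$algorithm]),
      row.names = NULL)
  }))
}
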