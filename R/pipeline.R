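#' End-to-end pipeline configuration
#'
#' Collects the sub-configurations of every stage around the published
#' defaults: 10-s analysis grid, 5- and 30-min feature windows, 6-h worry
#' horizon, 75/25 infant-level split, 5-fold cross-validated grid
#' {2,4,8,12} x {25,50,100,200} (off by default in favour of the selected
#' final parameters 100 trees / depth 4), and CRIB-II worry threshold 11.
#' One global seed deterministically derives every stage seed via
#' [derive_seed()].
#'
#' @param n_infants Cohort size to simulate.
#' @param seed Global pipeline seed.
#' @param generator [generator_config()] for the synthetic cohort; by
#'   default built from `n_infants` and a seed derived from `seed`.
#' @param feature A [feature_config()].
#' @param horizon_s Worry horizon (seconds).
#' @param period_s Analysis grid period (seconds).
#' @param train_fraction Infant-level training fraction.
#' @param params Final [model_params()] used when `use_grid_search` is off.
#' @param grid A [grid_search_spec()].
#' @param use_grid_search Run the cross-validated grid search instead of
#'   the fixed final parameters.
#' @param crib2_threshold CRIB-II worry threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_infants = 275,
                            seed = 1L,
                            generator = NULL,
                            feature = feature_config(),
                            horizon_s = 21600,
                            period_s = 10,
                            train_fraction = 0.75,
                            params = model_params(100L, 4L),
                            grid = grid_search_spec(),
                            use_grid_search = FALSE,
                            crib2_threshold = 11) {
  if (is.null(generator)) {
    generator <- generator_config(n_infants = n_infants,
                                  seed = derive_seed(seed, "generator"))
  }
  stopifnot(inherits(generator, "generator_config"),
            inherits(feature, "feature_config"),
            inherits(params, "model_params"),
            inherits(grid, "grid_search_spec"))
  structure(list(n_infants = generator$n_infants, seed = as.integer(seed),
                 generator = generator, feature = feature,
                 horizon_s = horizon_s, period_s = period_s,
                 train_fraction = train_fraction, params = params,
                 grid = grid, use_grid_search = isTRUE(use_grid_search),
                 crib2_threshold = crib2_threshold),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The file representation round-trips losslessly; unknown keys are
#' rejected rather than silently dropped.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) {
      if (is.list(v)) strip(v)
      else if (!is.null(names(v))) as.list(v)  # keep names as a YAML map
      else v
    })
  }
  writeLines(yaml::as.yaml(strip(config), precision = 15), path)
  invisible(path)
}

check_keys <- function(x, allowed, what) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort_ctx("unknown %s key(s): %s", what, paste(unknown, collapse = ", "))
  }
  x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top <- c("n_infants", "seed", "generator", "feature", "horizon_s", "period_s",
           "train_fraction", "params", "grid", "use_grid_search", "crib2_threshold")
  check_keys(raw, top, "pipeline config")
  rebuild <- function(args, fn, what) {
    check_keys(args, names(formals(fn)), what)
    args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
    do.call(fn, args)
  }
  gen <- rebuild(raw$generator, generator_config, "generator config")
  pipeline_config(
    n_infants = raw$n_infants, seed = raw$seed, generator = gen,
    feature = rebuild(raw$feature, feature_config, "feature config"),
    horizon_s = raw$horizon_s, period_s = raw$period_s,
    train_fraction = raw$train_fraction,
    params = rebuild(raw$params, model_params, "model params"),
    grid = rebuild(raw$grid, grid_search_spec, "grid spec"),
    use_grid_search = raw$use_grid_search,
    crib2_threshold = raw$crib2_threshold)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_ctx("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full mortality-risk pipeline
#'
#' simulate -> inclusion filter -> range filter -> infant-level split ->
#' split-wise mean imputation -> downsample -> featurize -> label ->
#' balance (training only) -> train (optionally grid-searched) ->
#' per-timepoint prediction on the held-out infants -> CRIB-II and
#' static-only logistic baselines -> per-timepoint and per-infant
#' evaluation. Fully reproducible from the configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (cohort CSV,
#'   predictions CSV, metrics JSON, ROC CSV, run manifest).
#' @param quiet Suppress stage logging.
#' @return List with `metrics` (per-timepoint and per-infant reports),
#'   `per_infant` (test-infant table), `predictions`, `model`, `params`,
#'   `split`, `counts`, and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  say("pipeline seed %d: simulating %d infants", config$seed, config$generator$n_infants)

  cohort <- run_stage("simulate", generate_cohort(config$generator))
  counts$simulated <- nrow(cohort)
  gen <- config$generator
  # the generator is a pure function of (infant, config), so streams can be
  # regenerated on demand instead of held for the whole run
  raw_stream <- function(rec) {
    apply_viable_ranges(inject_artifacts(simulate_vitals(rec, gen), gen))
  }

  cohort <- run_stage("filter", {
    # durations are carried on the cohort, so inclusion filtering only needs
    # stream presence, honoured by construction of the generator
    keep <- filter_cohort(cohort,
                          stats::setNames(vector("list", nrow(cohort)),
                                          cohort$infant_id))
    keep
  })
  counts$included <- nrow(cohort)
  counts$deaths <- sum(cohort$died)
  say("inclusion filter kept %d infants (%d deaths)", counts$included, counts$deaths)

  split <- run_stage("split", split_cohort(cohort, config$train_fraction, config$seed))
  say("infant-level split: %d train / %d test", length(split$train), length(split$test))
  if (length(split$test) == 0 || length(split$train) == 0) {
    abort_ctx("pipeline stage 'split' failed: empty train or test side")
  }

  # pass 1: pooled per-split imputation means (streams discarded as they go)
  means <- run_stage("preprocess", {
    out <- list()
    for (side in c("train", "test")) {
      acc <- NULL
      for (id in split[[side]]) {
        acc <- accumulate_channel_sums(acc, raw_stream(cohort[cohort$infant_id == id, ]))
      }
      out[[side]] <- means_from_sums(acc, side)
    }
    out
  })

  # pass 2: regenerate, impute, downsample, featurize one infant at a time
  say("building %d-feature matrix on the %g-s grid",
      length(feature_names(config$feature)), config$period_s)
  labeled <- run_stage("featurize", {
    per_infant_rows <- lapply(cohort$infant_id, function(id) {
      rec <- cohort[cohort$infant_id == id, ]
      side <- if (id %in% split$train) "train" else "test"
      s <- downsample_stream(impute_missing(raw_stream(rec), means[[side]]),
                             config$period_s)
      build_feature_matrix(stats::setNames(list(s), id), rec, config$feature)
    })
    m <- dplyr::bind_rows(per_infant_rows)
    rm(per_infant_rows)
    assign_labels(m, cohort, config$horizon_s, config$period_s)
  })
  counts$rows <- nrow(labeled)
  counts$worry_rows <- sum(labeled$label)
  say("%d rows labeled: %d worry / %d don't-worry", counts$rows,
      counts$worry_rows, counts$rows - counts$worry_rows)

  train_rows <- labeled[labeled$infant_id %in% split$train, ]
  test_rows <- labeled[labeled$infant_id %in% split$test, ]
  rm(labeled); gc(verbose = FALSE)

  params <- config$params
  grid_scores <- NULL
  if (config$use_grid_search) {
    gs <- run_stage("grid_search",
                    grid_search_cv(train_rows, config$grid, config$seed))
    params <- gs$best
    grid_scores <- gs$scores
    say("grid search selected %d trees, depth %d",
        params$n_estimators, params$max_depth)
  }
  params$seed <- derive_seed(config$seed, "forest")

  balanced <- run_stage("balance", balance_training_set(train_rows, config$seed))
  counts$balanced_rows <- nrow(balanced)
  model <- run_stage("train", train_classifier(balanced, params))
  predictions <- run_stage("predict", predict_timepoints(model, test_rows))

  pt_metrics <- run_stage("evaluate", {
    metrics_report("random_forest", "per_timepoint",
                   predictions$label, test_rows$label, predictions$probability)
  })

  per_infant <- run_stage("baseline", {
    test_cohort <- cohort[match(split$test, cohort$infant_id), ]
    train_cohort <- cohort[match(split$train, cohort$infant_id), ]
    statics <- function(x) dplyr::bind_rows(lapply(seq_len(nrow(x)),
                                                   function(i) as.list(encode_statics(x[i, ]))))
    lb <- fit_logistic_baseline(statics(train_cohort), train_cohort$died)
    lp <- predict(lb, statics(test_cohort))
    crib <- crib2_score(test_cohort$ga_weeks, test_cohort$birth_weight_g,
                        test_cohort$sex, test_cohort$admission_temp_c,
                        test_cohort$base_excess_mmol_l)
    agg <- lapply(split$test, function(id) {
      aggregate_per_infant(predictions[predictions$infant_id == id, ],
                           config$horizon_s, config$period_s)
    })
    tibble::tibble(
      infant_id = test_cohort$infant_id, died = test_cohort$died,
      rf_label = vapply(agg, `[[`, integer(1), "label"),
      rf_score = vapply(agg, `[[`, numeric(1), "score"),
      logistic_prob = lp, logistic_label = as.integer(lp >= 0.5),
      crib2_total = crib$total,
      crib2_worry = crib2_classify(crib$total, config$crib2_threshold))
  })

  metrics <- run_stage("evaluate",
                       dplyr::bind_rows(pt_metrics, compare_models(per_infant)))
  say("per-timepoint RF accuracy %.3f / AUC %.3f; per-infant RF AUC %.3f",
      pt_metrics$accuracy, pt_metrics$auc,
      metrics$auc[metrics$model == "random_forest" &
                    metrics$granularity == "per_infant"])

  result <- list(metrics = metrics, per_infant = per_infant,
                 predictions = predictions, model = model, params = params,
                 grid_scores = grid_scores, split = split, counts = counts,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_predictions_csv(predictions, file.path(out_dir, "predictions.csv"))
    write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
    roc_points <- dplyr::bind_rows(lapply(seq_len(nrow(metrics)), function(i) {
      cbind(model = metrics$model[i], granularity = metrics$granularity[i],
            metrics$roc[[i]])
    }))
    readr::write_csv(roc_points, file.path(out_dir, "roc_points.csv"))
    cfg_file <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, cfg_file)
    manifest <- list(
      package_version = as.character(utils::packageVersion("neoworry")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_file)),
      stage_seeds = list(generator = config$generator$seed,
                         split = derive_seed(config$seed, "split"),
                         balance = derive_seed(config$seed, "balance"),
                         forest = params$seed),
      counts = counts)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
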