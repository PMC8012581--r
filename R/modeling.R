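#' Infant-level train/test split
#'
#' Infants — never individual timepoints — are assigned to one side, so no
#' infant contributes rows to both. With 275 infants at the default
#' fraction the training side holds floor(0.75 * 275) = 206.
#'
#' @param infants Cohort tibble (or anything with an `infant_id` column).
#' @param train_fraction Fraction of infants assigned to training.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
split_cohort <- function(infants, train_fraction = 0.75, seed = 1L) {
  ids <- infants$infant_id
  if (length(ids) < 2) abort_ctx("need at least 2 infants to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_ctx("`train_fraction` must lie strictly between 0 and 1")
  }
  n_train <- floor(train_fraction * length(ids))
  train <- with_seed(derive_seed(seed, "split"), sample(ids, n_train))
  list(train = train, test = setdiff(ids, train))
}

#' Final classifier hyper-parameters
#'
#' @param n_estimators Number of trees (default 100).
#' @param max_depth Maximum tree depth (default 4).
#' @param seed Integer seed.
#' @return List of class `model_params`.
#' @export
model_params <- function(n_estimators = 100L, max_depth = 4L, seed = 1L) {
  stopifnot(n_estimators >= 1, max_depth >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "model_params")
}

#' Hyper-parameter grid for cross-validated selection
#'
#' @param max_depth Candidate maximum depths.
#' @param n_estimators Candidate tree counts.
#' @param k Number of cross-validation folds.
#' @return List of class `grid_search_spec`.
#' @export
grid_search_spec <- function(max_depth = c(2L, 4L, 8L, 12L),
                             n_estimators = c(25L, 50L, 100L, 200L),
                             k = 5L) {
  stopifnot(length(max_depth) >= 1, length(n_estimators) >= 1, k >= 2)
  structure(list(max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators), k = as.integer(k)),
            class = "grid_search_spec")
}

# Partition infant ids into k near-equal folds, seeded.
make_infant_folds <- function(ids, k, seed) {
  ids <- unique(ids)
  if (k > length(ids)) abort_ctx("k = %d exceeds the number of infants (%d)", k, length(ids))
  shuffled <- with_seed(derive_seed(seed, "folds"), sample(ids))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Grid search with infant-level k-fold cross-validation
#'
#' Every (max_depth, n_estimators) combination is fitted k times, each time
#' training on k-1 infant folds (balanced by worry-count subsampling inside
#' the training folds only) and scored on the held-out fold's unbalanced
#' rows. A combination's score is its mean held-out accuracy; ties break by
#' higher mean AUC, then smaller depth. Folds partition infants, never
#' rows, so no infant straddles a fold boundary.
#'
#' @param dataset Labeled feature matrix (training split, unbalanced).
#' @param spec A [grid_search_spec()].
#' @param seed Integer seed.
#' @return List with `best` ([model_params()]) and `scores`, a tibble of
#'   per-combination per-fold accuracy and AUC.
#' @export
grid_search_cv <- function(dataset, spec = grid_search_spec(), seed = 1L) {
  stopifnot(inherits(spec, "grid_search_spec"))
  folds <- make_infant_folds(dataset$infant_id, spec$k, seed)
  combos <- expand.grid(max_depth = spec$max_depth,
                        n_estimators = spec$n_estimators)
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    for (fi in seq_len(spec$k)) {
      held <- dataset$infant_id %in% folds[[fi]]
      train <- balance_training_set(dataset[!held, ],
                                    seed = derive_seed(seed, sprintf("cv/%d/%d", ci, fi)))
      params <- model_params(combos$n_estimators[ci], combos$max_depth[ci],
                             seed = derive_seed(seed, sprintf("cvfit/%d/%d", ci, fi)))
      fit <- train_classifier(train, params)
      pred <- predict_timepoints(fit, dataset[held, ])
      truth <- dataset$label[held]
      acc <- mean(pred$label == truth)
      auc <- if (length(unique(truth)) == 2) roc_auc(pred$probability, truth)$auc else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        max_depth = combos$max_depth[ci], n_estimators = combos$n_estimators[ci],
        fold = fi, accuracy = acc, auc = auc)
    }
  }
  scores <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(scores, .data$max_depth, .data$n_estimators),
    accuracy = mean(.data$accuracy), auc = mean(.data$auc, na.rm = TRUE),
    .groups = "drop")
  best_row <- summary[order(-summary$accuracy, -summary$auc, summary$max_depth), ][1, ]
  list(best = model_params(best_row$n_estimators, best_row$max_depth, seed = seed),
       scores = scores)
}

#' Train the per-timepoint worry classifier
#'
#' Fits a random forest (trees grown on bootstrap samples, a random
#' predictor subset considered at each split) on a balanced labeled
#' feature matrix. The per-timepoint worry probability is the fraction of
#' trees voting worry; feature importances are mean decreases in Gini
#' impurity, normalised to sum to one.
#'
#' @param dataset Balanced labeled feature matrix with no missing values.
#' @param params A [model_params()].
#' @return Object of class `worry_model`.
#' @export
train_classifier <- function(dataset, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  if (nrow(dataset) == 0) abort_ctx("cannot train on an empty dataset")
  if (length(unique(dataset$label)) < 2) {
    abort_ctx("training data must contain both classes")
  }
  feats <- setdiff(names(dataset), c("infant_id", "t_s", "label"))
  x <- as.data.frame(dataset[, feats])
  y <- factor(dataset$label, levels = c(0L, 1L))
  fit <- ranger::ranger(x = x, y = y,
                        num.trees = params$n_estimators,
                        max.depth = params$max_depth,
                        importance = "impurity",
                        seed = params$seed,
                        num.threads = 1)
  imp <- pmax(fit$variable.importance, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(kind = "random_forest", forest = fit, params = params,
                 feature_names = feats, importance = imp),
            class = "worry_model")
}

#' @export
print.worry_model <- function(x, ...) {
  cat(sprintf("<worry_model> random forest: %d trees, max depth %d, %d features\n",
              x$params$n_estimators, x$params$max_depth, length(x$feature_names)))
  top <- sort(x$importance, decreasing = TRUE)[seq_len(min(5, length(x$importance)))]
  cat("  top importances:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Per-timepoint worry predictions
#'
#' The worry probability at each timepoint is the fraction of trees voting
#' worry; the binary prediction is worry when that fraction reaches 0.5.
#' Prediction is chunked so per-tree vote matrices never grow with the
#' full input.
#'
#' @param model A [train_classifier()] fit.
#' @param matrix Feature matrix whose feature columns match the model's.
#' @param chunk_size Rows scored per block.
#' @return Tibble `infant_id`, `t_s`, `probability`, `label`.
#' @export
predict_timepoints <- function(model, matrix, chunk_size = 200000L) {
  stopifnot(inherits(model, "worry_model"))
  missing_cols <- setdiff(model$feature_names, names(matrix))
  if (length(missing_cols) > 0) {
    abort_ctx("feature matrix lacks model column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(matrix[, model$feature_names])
  n <- nrow(x)
  worry_idx <- 2L  # factor level "1"
  prob <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    votes <- stats::predict(model$forest, data = x[s:e, , drop = FALSE],
                            predict.all = TRUE, num.threads = 1)$predictions
    prob[s:e] <- rowMeans(votes == worry_idx)
  }
  tibble::tibble(infant_id = matrix$infant_id, t_s = matrix$t_s,
                 probability = prob, label = as.integer(prob >= 0.5))
}

#' Depth of every tree in a fitted forest
#'
#' @param model A `worry_model`.
#' @return Integer vector of per-tree depths.
#' @export
tree_depths <- function(model) {
  stopifnot(inherits(model, "worry_model"))
  vapply(seq_len(model$forest$num.trees), function(i) {
    info <- ranger::treeInfo(model$forest, i)
    depth <- stats::setNames(rep(0L, nrow(info)), info$nodeID)
    for (r in seq_len(nrow(info))) {
      kids <- c(info$leftChild[r], info$rightChild[r])
      kids <- kids[!is.na(kids)]
      depth[as.character(kids)] <- depth[[as.character(info$nodeID[r])]] + 1L
    }
    max(depth)
  }, integer(1))
}
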