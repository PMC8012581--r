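test_that("cohort splits are infant-level partitions of the stated size", {
  infants <- dplyr::bind_rows(lapply(1:275, function(i)
    make_infant(sprintf("P%03d", i))))
  sp <- split_cohort(infants, 0.75, seed = 3)
  expect_length(sp$train, 206)
  expect_length(sp$test, 69)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), infants$infant_id)
  expect_identical(split_cohort(infants, 0.75, seed = 3), sp)
  expect_false(identical(split_cohort(infants, 0.75, seed = 4)$train, sp$train))
  expect_error(split_cohort(infants, 1.2, seed = 1), "between 0 and 1")
  expect_error(split_cohort(infants[1, ], 0.5, seed = 1), "at least 2")
})

test_that("the classifier respects tree count, depth, and vote semantics", {
  ds <- make_toy_dataset()
  fit <- train_classifier(ds, model_params(100L, 4L, seed = 5))
  expect_equal(fit$forest$num.trees, 100)
  expect_true(all(tree_depths(fit) <= 4))
  # perfectly separable rule (worry iff HR_mean_300 < 80) is learned exactly
  pred <- predict_timepoints(fit, ds)
  expect_equal(mean(pred$label == ds$label), 1.0)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  # importances: non-negative, sum to one, and the signal feature dominates
  expect_true(all(fit$importance >= 0))
  expect_equal(sum(fit$importance), 1)
  expect_gt(fit$importance[["HR_mean_300"]], fit$importance[["noise"]])
  # single tree => vote fraction is 0 or 1
  one <- train_classifier(ds, model_params(1L, 4L, seed = 5))
  expect_true(all(predict_timepoints(one, ds)$probability %in% c(0, 1)))
  # reproducibility and error cases
  expect_identical(predict_timepoints(train_classifier(ds, model_params(50L, 3L, seed = 9)), ds),
                   predict_timepoints(train_classifier(ds, model_params(50L, 3L, seed = 9)), ds))
  expect_error(train_classifier(ds[0, ], model_params()), "empty")
  expect_error(train_classifier(ds[ds$label == 0, ], model_params()), "both classes")
  expect_error(predict_timepoints(fit, ds[, 1:3]), "lacks model column")
})

test_that("vote fractions equal the brute-force mean of per-tree votes", {
  ds <- make_toy_dataset(n_infants = 6, rows_per_infant = 50)
  fit <- train_classifier(ds, model_params(25L, 4L, seed = 2))
  rows <- ds[sample.int(nrow(ds), 100), ]
  got <- predict_timepoints(fit, rows)$probability
  votes <- predict(fit$forest,
                   data = as.data.frame(rows[, fit$feature_names]),
                   predict.all = TRUE, num.threads = 1)$predictions
  oracle <- apply(votes, 1, function(v) mean(v == 2))
  expect_equal(got, oracle)
})

test_that("grid search evaluates every combination with infant-disjoint folds", {
  ds <- make_toy_dataset(n_infants = 20, rows_per_infant = 40)
  # blur the rule so deeper trees can differ from shallow ones
  withr::with_seed(3, ds$HR_mean_300 <- ds$HR_mean_300 + rnorm(nrow(ds), 0, 12))
  # the half-worry toy labels make some training folds worry-heavy, which
  # balance_training_set reports by design; that path is asserted separately
  gs <- suppressWarnings(grid_search_cv(ds, grid_search_spec(), seed = 6))
  expect_equal(nrow(gs$scores), 16 * 5)
  expect_equal(nrow(unique(gs$scores[, c("max_depth", "n_estimators")])), 16)
  expect_true(all(table(gs$scores$max_depth, gs$scores$n_estimators) == 5))
  expect_s3_class(gs$best, "model_params")
  expect_true(gs$best$max_depth %in% c(2, 4, 8, 12))
  expect_true(gs$best$n_estimators %in% c(25, 50, 100, 200))
  # learnable signal: the chosen combination clearly beats coin-flipping
  best_rows <- gs$scores[gs$scores$max_depth == gs$best$max_depth &
                           gs$scores$n_estimators == gs$best$n_estimators, ]
  expect_gt(mean(best_rows$accuracy), 0.5)
  # folds partition infants, never rows
  folds <- neoworry:::make_infant_folds(ds$infant_id, 5, seed = 6)
  expect_setequal(unlist(folds), unique(ds$infant_id))
  expect_equal(sum(lengths(folds)), length(unique(ds$infant_id)))
  expect_error(neoworry:::make_infant_folds(ds$infant_id, 21, 1), "exceeds")
  # single-combination grid returns that combination
  one <- suppressWarnings(
    grid_search_cv(ds, grid_search_spec(max_depth = 4L,
                                        n_estimators = 25L, k = 5L),
                   seed = 6))
  expect_equal(one$best$max_depth, 4L)
  expect_equal(one$best$n_estimators, 25L)
})

test_that("birth weight and gestational age rank among the top importances", {
  # on default GA/BW-driven synthetic cohorts, across five seeded runs
  runs <- ordering_runs()
  rank_ga <- vapply(runs, `[[`, integer(1), "rank_ga")
  rank_bw <- vapply(runs, `[[`, integer(1), "rank_bw")
  expect_lte(median(rank_ga), 5)
  expect_lte(median(rank_bw), 5)
})
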