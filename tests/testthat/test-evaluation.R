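test_that("confusion metrics reproduce hand-computed contingency tables", {
  truth <- rep(c(1, 0), c(10, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))  # TP8 FN2 FP1 TN9
  m <- confusion_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  p <- confusion_metrics(truth, truth)
  expect_equal(unlist(p), c(accuracy = 1, sensitivity = 1, specificity = 1))
  inv <- confusion_metrics(1 - pred, truth)
  expect_equal(inv$sensitivity, 0.2)
  expect_equal(inv$specificity, 0.1)
  expect_equal(inv$accuracy, 0.15)
  expect_error(confusion_metrics(pred, rep(0, 20)), "no positive")
  expect_error(confusion_metrics(pred, rep(1, 20)), "no negative")
  expect_error(confusion_metrics(pred, truth[1:5]), "length")
})

test_that("trapezoid AUC equals pairwise concordance and behaves under nulls", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  # O(n^2) oracle on 200 random score/label pairs, with ties
  withr::with_seed(12, {
    scores <- round(rnorm(200), 1)  # rounding forces ties
    truth <- rbinom(200, 1, 0.4)
  })
  r <- roc_auc(scores, truth)
  expect_equal(r$auc, brute_auc(scores, truth), tolerance = 1e-12)
  # ROC anchored at (0,0) and (1,1), coordinates non-decreasing
  expect_equal(unlist(r$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(qlogis(plogis(scores)), truth)$auc, r$auc)
  expect_equal(roc_auc(exp(scores), truth)$auc, r$auc)
  # label-independent scores give AUC near 1/2
  withr::with_seed(13, {
    s0 <- rnorm(10000); t0 <- rbinom(10000, 1, 0.5)
  })
  n1 <- sum(t0); n0 <- sum(1 - t0)
  null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(s0, t0)$auc - 0.5), 3 * null_sd)
  expect_error(roc_auc(s0, rep(1, 10000)), "both classes")
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("per-infant aggregation takes a majority over the final window", {
  trace <- function(labels, probs = labels) {
    tibble::tibble(t_s = seq(0, by = 10, length.out = length(labels)),
                   probability = probs, label = as.integer(labels))
  }
  # all worry in the final window
  expect_equal(aggregate_per_infant(trace(rep(1, 3000)))$label, 1L)
  # majority arithmetic at 2,160 window points
  w <- c(rep(0, 840), rep(1, 1081), rep(0, 2160 - 1081))
  expect_equal(aggregate_per_infant(trace(w))$label, 1L)
  w2 <- c(rep(0, 840), rep(1, 1079), rep(0, 2160 - 1079))
  expect_equal(aggregate_per_infant(trace(w2))$label, 0L)
  # exact tie resolves to worry
  w3 <- c(rep(0, 840), rep(1, 1080), rep(0, 2160 - 1080))
  expect_equal(aggregate_per_infant(trace(w3))$label, 1L)
  # only the final window matters; order within it does not
  withr::with_seed(2, {
    lead <- rbinom(500, 1, 0.5)
    win <- rbinom(2160, 1, 0.6)
    base <- aggregate_per_infant(trace(c(lead, win)))
    perm <- aggregate_per_infant(trace(c(1 - lead, sample(win))))
    expect_equal(base$label, perm$label)
    expect_equal(base$score, perm$score, tolerance = 1e-12)
  })
  # short traces use everything available
  expect_equal(aggregate_per_infant(trace(c(1, 1, 0)))$label, 1L)
  expect_equal(aggregate_per_infant(trace(rep(0.25, 10), probs = rep(0.25, 10)))$score, 0.25)
  expect_error(aggregate_per_infant(trace(integer(0))), "empty")
})

test_that("rolling prediction traces average over the trailing hour", {
  expect_equal(rolling_trace(rep(0, 500)), rep(0, 500))
  expect_equal(rolling_trace(rep(1, 500)), rep(1, 500))
  alt <- rep(c(0, 1), 400)
  tr <- rolling_trace(alt)
  expect_equal(tr[400:800], rep(0.5, 401))  # steady state over full windows
  expect_true(all(tr >= 0 & tr <= 1))
  expect_error(rolling_trace(numeric(0)), "empty")
})

test_that("model comparison reports one row per model on shared infants", {
  per_infant <- tibble::tibble(
    infant_id = sprintf("P%02d", 1:10),
    died = rep(c(TRUE, FALSE), c(3, 7)),
    rf_label = c(1, 1, 1, rep(0, 7)),
    rf_score = c(0.9, 0.8, 0.7, seq(0.3, 0.0, length.out = 7)),
    logistic_label = c(1, 1, 1, rep(0, 7)),
    logistic_prob = c(0.95, 0.9, 0.6, seq(0.4, 0.05, length.out = 7)),
    crib2_total = c(20, 15, 12, 10, 9, 8, 6, 5, 3, 1),
    crib2_worry = c(1, 1, 1, rep(0, 7)))
  rep_ <- compare_models(per_infant)
  expect_equal(nrow(rep_), 3)
  expect_setequal(rep_$model, c("crib2", "logistic", "random_forest"))
  expect_true(all(rep_$granularity == "per_infant"))
  # perfect per-infant scores give three AUC 1.0 rows
  expect_equal(rep_$auc, rep(1, 3))
  expect_equal(rep_$accuracy, rep(1, 3))
  expect_error(compare_models(per_infant[, -3]), "lacks column")
})
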