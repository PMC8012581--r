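#' Confusion-matrix metrics
#'
#' Worry (1) is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/N.
#'
#' @param predicted Binary predictions.
#' @param truth Binary ground truth of equal length.
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (!all(c(predicted, truth) %in% 0:1)) abort_ctx("labels must be binary 0/1")
  if (sum(truth == 1) == 0) abort_ctx("no positive cases; sensitivity undefined")
  if (sum(truth == 0) == 0) abort_ctx("no negative cases; specificity undefined")
  tp <- sum(predicted == 1 & truth == 1); fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0); fp <- sum(predicted == 1 & truth == 0)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' ROC curve and trapezoidal AUC
#'
#' The ROC is swept over every distinct score threshold (higher scores
#' mean more worry), anchored at (0,0) and (1,1); the AUC is its
#' trapezoidal area, which with this construction equals the tie-corrected
#' concordance probability between positive and negative scores.
#'
#' @param scores Continuous (or ordinal) scores.
#' @param truth Binary ground truth, both classes present.
#' @return List with `auc` and `roc`, a tibble of `(fpr, tpr)` points in
#'   sweep order.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) abort_ctx("ROC requires both classes in the truth labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # collapse tied scores so each threshold is a distinct score value
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = tibble::tibble(fpr = fpr, tpr = tpr))
}

#' Collapse per-timepoint predictions to one per-infant call
#'
#' The per-infant label is the majority of the binary per-timepoint
#' predictions over the record's final window (default 6 h; all
#' predictions when the record is shorter), with exact ties resolved to
#' worry — the clinically conservative choice. The per-infant continuous
#' score, used for per-infant ROC analysis, is the mean worry probability
#' over the same window.
#'
#' @param trace Tibble of one infant's predictions ordered by time, with
#'   columns `probability` and `label` (see [predict_timepoints()]).
#' @param window_s Aggregation window in seconds.
#' @param period_s Grid period in seconds.
#' @return List with `label` (0/1) and `score` (mean probability).
#' @export
aggregate_per_infant <- function(trace, window_s = 21600, period_s = 10) {
  if (nrow(trace) == 0) abort_ctx("cannot aggregate an empty prediction trace")
  m <- min(nrow(trace), window_s / period_s)
  tail_rows <- trace[(nrow(trace) - m + 1L):nrow(trace), ]
  list(label = as.integer(mean(tail_rows$label) >= 0.5),
       score = mean(tail_rows$probability))
}

#' Rolling mean of binary predictions
#'
#' Trailing one-hour (by default) average of the per-timepoint binary
#' predictions, shrinking at the start of the record — the smoothed trace
#' plotted over an infant's stay.
#'
#' @param labels Binary per-timepoint predictions on the analysis grid.
#' @param window_s Smoothing window in seconds.
#' @param period_s Grid period in seconds.
#' @return Numeric series in [0,1], same length as `labels`.
#' @export
rolling_trace <- function(labels, window_s = 3600, period_s = 10) {
  if (length(labels) == 0) abort_ctx("empty prediction series")
  rolling_stats(as.numeric(labels), window_s, period_s)$mean
}

metrics_report <- function(model, granularity, predicted, truth, scores) {
  cm <- confusion_metrics(predicted, truth)
  roc <- roc_auc(scores, truth)
  tibble::tibble(model = model, granularity = granularity,
                 accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, auc = roc$auc,
                 roc = list(roc$roc))
}

#' Compare the forest, logistic, and CRIB-II models per infant
#'
#' All three models are evaluated on the same infants against the
#' eventual-death outcome (a worry call is correct when the infant
#' eventually died). The CRIB-II ROC is swept over its integer score
#' thresholds; the forest's per-infant score is the final-window mean
#' worry probability from [aggregate_per_infant()].
#'
#' @param per_infant Tibble with one row per test infant: `infant_id`,
#'   `died`, `rf_label`, `rf_score`, `logistic_label`, `logistic_prob`,
#'   `crib2_worry`, `crib2_total`.
#' @return Tibble of metrics reports (one row per model) with an ROC
#'   list-column.
#' @export
compare_models <- function(per_infant) {
  need <- c("infant_id", "died", "rf_label", "rf_score",
            "logistic_label", "logistic_prob", "crib2_worry", "crib2_total")
  missing_cols <- setdiff(need, names(per_infant))
  if (length(missing_cols) > 0) {
    abort_ctx("per-infant table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  truth <- as.integer(per_infant$died)
  dplyr::bind_rows(
    metrics_report("crib2", "per_infant", per_infant$crib2_worry, truth,
                   per_infant$crib2_total),
    metrics_report("logistic", "per_infant", per_infant$logistic_label, truth,
                   per_infant$logistic_prob),
    metrics_report("random_forest", "per_infant", per_infant$rf_label, truth,
                   per_infant$rf_score))
}
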