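#' Assign per-timepoint worry labels
#'
#' A timepoint is labeled worry (1) when its infant died and the death
#' occurred within the horizon after the timestamp:
#' `0 < death_time_s - t_s <= horizon_s`. All other timepoints, and every
#' timepoint of a survivor, are don't-worry (0). With the 10-s grid and the
#' default 6-h horizon, a deceased infant with at least a full horizon of
#' pre-death data contributes exactly 2,160 worry rows.
#'
#' @param matrix Feature matrix (see [build_feature_matrix()]).
#' @param infants Cohort tibble with `died` and `death_time_s`.
#' @param horizon_s Worry horizon in seconds (default 21,600 = 6 h); must
#'   be a multiple of the grid period.
#' @param period_s Analysis grid period in seconds.
#' @return The matrix with an integer `label` column; the horizon is kept
#'   in attribute `horizon_s`.
#' @export
assign_labels <- function(matrix, infants, horizon_s = 21600, period_s = 10) {
  if (horizon_s <= 0 || horizon_s %% period_s != 0) {
    abort_ctx("`horizon_s` must be a positive multiple of the %g-s grid period", period_s)
  }
  dead <- infants[infants$died, ]
  if (any(!is.finite(dead$death_time_s))) {
    abort_ctx("deceased infant(s) missing death_time_s: %s",
              paste(dead$infant_id[!is.finite(dead$death_time_s)], collapse = ", "))
  }
  death_of <- stats::setNames(rep(Inf, nrow(infants)), infants$infant_id)
  death_of[dead$infant_id] <- dead$death_time_s
  gap <- death_of[matrix$infant_id] - matrix$t_s
  matrix$label <- as.integer(gap > 0 & gap <= horizon_s)
  attr(matrix, "horizon_s") <- horizon_s
  matrix
}

#' Balance a labeled training set by majority-class subsampling
#'
#' Keeps every worry row and draws a uniform random subsample (without
#' replacement) of don't-worry rows of equal size. Applied to training
#' data only; test-set class imbalance is left untouched, as it will exist
#' in any live data stream.
#'
#' @param dataset Labeled feature matrix.
#' @param seed Integer seed for the subsample.
#' @return Balanced dataset (worry rows first); row keys are a subset of
#'   the input's.
#' @export
balance_training_set <- function(dataset, seed) {
  worry <- which(dataset$label == 1L)
  calm <- which(dataset$label == 0L)
  if (length(worry) == 0) abort_ctx("cannot balance a training set with no worry rows")
  if (length(worry) > length(calm)) {
    warning("worry rows outnumber don't-worry rows; returning dataset unchanged")
    return(dataset)
  }
  keep <- with_seed(derive_seed(seed, "balance"),
                    sample(calm, length(worry), replace = FALSE))
  out <- dataset[c(worry, keep), ]
  attr(out, "horizon_s") <- attr(dataset, "horizon_s")
  out
}
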