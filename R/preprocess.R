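#' Viable physiologic ranges for each vital-sign channel
#'
#' Closed intervals outside which a sample is treated as artifact: HR
#' [0, 250] beats/min, RR [0, 120] breaths/min, SpO2 [0, 100] %, all BP
#' channels [10, 90] mmHg.
#'
#' @return Named list of length-2 numeric vectors (lower, upper).
#' @export
viable_ranges <- function() {
  list(HR = c(0, 250), RR = c(0, 120), SPO2 = c(0, 100),
       BP_S = c(10, 90), BP_M = c(10, 90), BP_D = c(10, 90))
}

#' Apply cohort inclusion criteria
#'
#' Retains infants born before 32 completed weeks with at least 80 h
#' (288,000 s) of recorded vital-sign data. Order is preserved; every
#' infant must have an associated stream.
#'
#' @param infants Cohort tibble.
#' @param streams Named list of streams keyed by `infant_id`.
#' @return The retained subset of `infants`.
#' @export
filter_cohort <- function(infants, streams) {
  missing_stream <- setdiff(infants$infant_id, names(streams))
  if (length(missing_stream) > 0) {
    abort_ctx("no vital-sign stream for infant(s): %s",
              paste(missing_stream, collapse = ", "))
  }
  infants[infants$ga_weeks < 32 & infants$record_duration_s >= 288000, ]
}

#' Replace out-of-range samples with missing markers
#'
#' Every sample falling outside its channel's closed viable interval
#' becomes `NA`; in-range samples (including boundary values) pass through
#' untouched. Idempotent.
#'
#' @param stream Vital-sign stream tibble.
#' @param ranges Named list as from [viable_ranges()].
#' @return The range-filtered stream.
#' @export
apply_viable_ranges <- function(stream, ranges = viable_ranges()) {
  chans <- setdiff(names(stream), "t_s")
  uncovered <- setdiff(chans, names(ranges))
  if (length(uncovered) > 0) {
    abort_ctx("no viable range configured for channel(s): %s",
              paste(uncovered, collapse = ", "))
  }
  for (ch in chans) {
    r <- ranges[[ch]]
    x <- stream[[ch]]
    x[!is.na(x) & (x < r[1] | x > r[2])] <- NA_real_
    stream[[ch]] <- x
  }
  stream
}

#' Pooled per-channel imputation means for one data split
#'
#' The arithmetic mean of all non-missing samples of each channel, pooled
#' across the split's infants. Training and testing splits get their own
#' means so no information crosses the split boundary.
#'
#' @param streams Named list of (range-filtered) streams.
#' @param split Label recorded with the means, e.g. `"train"`.
#' @return Object of class `imputation_means`: named channel means plus the
#'   split label.
#' @export
compute_imputation_means <- function(streams, split = "train") {
  stopifnot(length(streams) >= 1)
  acc <- NULL
  for (s in streams) acc <- accumulate_channel_sums(acc, s)
  means_from_sums(acc, split)
}

# Streaming accumulator for pooled channel sums/counts, so split means can
# be formed without holding every 1-Hz stream in memory at once.
accumulate_channel_sums <- function(acc, stream) {
  chans <- setdiff(names(stream), "t_s")
  if (is.null(acc)) {
    acc <- list(sums = stats::setNames(numeric(length(chans)), chans),
                counts = stats::setNames(numeric(length(chans)), chans))
  }
  for (ch in chans) {
    x <- stream[[ch]]
    acc$sums[ch] <- acc$sums[ch] + sum(x, na.rm = TRUE)
    acc$counts[ch] <- acc$counts[ch] + sum(!is.na(x))
  }
  acc
}

means_from_sums <- function(acc, split) {
  empty <- names(acc$counts)[acc$counts == 0]
  if (length(empty) > 0) {
    abort_ctx("channel(s) entirely missing in the %s split: %s",
              split, paste(empty, collapse = ", "))
  }
  structure(list(means = acc$sums / acc$counts, split = split),
            class = "imputation_means")
}

#' @export
print.imputation_means <- function(x, ...) {
  cat(sprintf("<imputation_means> split = %s\n", x$split))
  print(round(x$means, 2))
  invisible(x)
}

#' Fill missing samples with split-level channel means
#'
#' @param stream Range-filtered stream.
#' @param means An `imputation_means` object for the stream's split.
#' @return Stream with no missing samples; observed values unchanged.
#' @export
impute_missing <- function(stream, means) {
  stopifnot(inherits(means, "imputation_means"))
  chans <- setdiff(names(stream), "t_s")
  absent <- setdiff(chans, names(means$means))
  if (length(absent) > 0) {
    abort_ctx("no imputation mean for channel(s): %s",
              paste(absent, collapse = ", "))
  }
  for (ch in chans) {
    x <- stream[[ch]]
    x[is.na(x)] <- means$means[[ch]]
    stream[[ch]] <- x
  }
  stream
}

#' Downsample a 1-Hz stream to the analysis grid
#'
#' Decimation: the output keeps the instantaneous sample at
#' `t = 0, period_s, 2*period_s, ...`, giving
#' `floor(duration / period_s) + 1` rows. The 1-Hz source is already a
#' time-integrated mean, so no additional averaging is applied.
#'
#' @param stream Stream on a 1-s grid starting at `t = 0`.
#' @param period_s Analysis period in seconds (default 10).
#' @return Stream on the coarse grid, attributes preserved.
#' @export
downsample_stream <- function(stream, period_s = 10) {
  if (!is.numeric(period_s) || period_s < 1) {
    abort_ctx("`period_s` must be a positive number of seconds")
  }
  out <- stream[stream$t_s %% period_s == 0, ]
  attr(out, "infant_id") <- attr(stream, "infant_id")
  attr(out, "bp_source") <- attr(stream, "bp_source")
  out
}
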