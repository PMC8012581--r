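#' Feature-extraction configuration
#'
#' Defines which dynamic channels, rolling statistics, and window lengths
#' enter the per-timepoint feature matrix, together with the encoded static
#' factors. The default — five channels (HR, RR, SpO2, systolic and mean
#' BP) times three statistics (rolling mean, rolling SD, absolute z-score)
#' times two windows (5 min, 30 min), plus four static factors — yields
#' exactly 34 features.
#'
#' @param dynamic_channels Ordered channel names.
#' @param statistics Ordered subset of `c("mean", "sd", "absz")`.
#' @param window_lengths_s Ordered window lengths in seconds; each must be
#'   a positive multiple of the analysis period.
#' @param static_factors Ordered static feature names.
#' @param period_s Analysis grid period in seconds.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(dynamic_channels = c("HR", "RR", "SPO2", "BP_S", "BP_M"),
                           statistics = c("mean", "sd", "absz"),
                           window_lengths_s = c(300, 1800),
                           static_factors = c("ga_weeks", "sex_code",
                                              "race_code", "birth_weight_g"),
                           period_s = 10) {
  stopifnot(length(dynamic_channels) > 0,
            all(statistics %in% c("mean", "sd", "absz")),
            all(window_lengths_s > 0))
  if (any(window_lengths_s %% period_s != 0)) {
    abort_ctx("every window length must be a multiple of the %g-s period", period_s)
  }
  structure(list(dynamic_channels = dynamic_channels, statistics = statistics,
                 window_lengths_s = window_lengths_s,
                 static_factors = static_factors, period_s = period_s),
            class = "feature_config")
}

#' Ordered feature names implied by a configuration
#'
#' Static factors first, then `<channel>_<stat>_<window>` for each channel,
#' window, and statistic.
#'
#' @param config A [feature_config()].
#' @return Character vector; length 34 at defaults.
#' @export
feature_names <- function(config = feature_config()) {
  dyn <- unlist(lapply(config$dynamic_channels, function(ch) {
    unlist(lapply(config$window_lengths_s, function(w) {
      paste(ch, config$statistics, w, sep = "_")
    }))
  }))
  c(config$static_factors, dyn)
}

#' Trailing rolling mean, SD, and absolute z-score
#'
#' Statistics over the trailing window of `window_s / period_s` samples
#' ending at (and including) each timepoint; at the start of a record the
#' window shrinks to the available history. The SD is the sample
#' (denominator n-1) standard deviation, defined as 0 when fewer than two
#' samples are in the window; the absolute z-score is
#' `|x - mean| / sd` when `sd > 0` and 0 otherwise.
#'
#' @param x Numeric series on the analysis grid, no missing values.
#' @param window_s Window length in seconds.
#' @param period_s Grid period in seconds.
#' @return List with components `mean`, `sd`, `absz`, each the length of `x`.
#' @export
rolling_stats <- function(x, window_s, period_s = 10) {
  if (window_s %% period_s != 0 || window_s <= 0) {
    abort_ctx("`window_s` must be a positive multiple of the %g-s grid period", period_s)
  }
  if (anyNA(x)) abort_ctx("rolling statistics require a series with no missing values")
  w <- as.integer(window_s / period_s)
  n <- length(x)
  if (n == 0) return(list(mean = numeric(0), sd = numeric(0), absz = numeric(0)))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- seq_len(n)
  lag <- pmax(i - w, 0L)
  nw <- i - lag
  s1 <- cs - c(0, cs)[lag + 1L]
  s2 <- cs2 - c(0, cs2)[lag + 1L]
  m <- s1 / nw
  var <- pmax(0, (s2 - nw * m^2) / pmax(nw - 1L, 1L))
  sd <- ifelse(nw >= 2, sqrt(var), 0)
  absz <- ifelse(sd > 0, abs(x - m) / sd, 0)
  list(mean = m, sd = sd, absz = absz)
}

#' Encode static factors as numeric features
#'
#' Gestational age and birth weight pass through; sex and race map to
#' integer codes (`male = 0, female = 1`; `white = 0, black = 1,
#' asian = 2, unknown = 3`). Integer codes (not one-hot) keep the static
#' block at exactly four columns.
#'
#' @param infant One-row cohort tibble.
#' @return Named numeric vector `ga_weeks, sex_code, race_code, birth_weight_g`.
#' @export
encode_statics <- function(infant) {
  sex_code <- match(infant$sex, SEX_LEVELS) - 1L
  race_code <- match(infant$race, RACE_LEVELS) - 1L
  if (is.na(sex_code)) abort_ctx("unknown sex category: %s", infant$sex)
  if (is.na(race_code)) abort_ctx("unknown race category: %s", infant$race)
  c(ga_weeks = as.numeric(infant$ga_weeks), sex_code = as.numeric(sex_code),
    race_code = as.numeric(race_code),
    birth_weight_g = as.numeric(infant$birth_weight_g))
}

#' Invert the static-factor encoding
#'
#' @param codes Named vector as from [encode_statics()].
#' @return List with `ga_weeks`, `sex`, `race`, `birth_weight_g`.
#' @export
decode_statics <- function(codes) {
  list(ga_weeks = as.integer(codes[["ga_weeks"]]),
       sex = SEX_LEVELS[codes[["sex_code"]] + 1L],
       race = RACE_LEVELS[codes[["race_code"]] + 1L],
       birth_weight_g = codes[["birth_weight_g"]])
}

#' Build the per-timepoint feature matrix
#'
#' One row per (infant, timepoint) on the analysis grid; columns are the
#' encoded static factors followed by every rolling statistic of every
#' dynamic channel and window. For deceased infants the timepoint at the
#' death instant is excluded, so records end strictly before death.
#'
#' @param streams Named list of preprocessed streams (no missing values,
#'   on the analysis grid), keyed by `infant_id`.
#' @param infants Cohort tibble covering every stream.
#' @param config A [feature_config()].
#' @return Tibble with `infant_id`, `t_s`, and the feature columns of
#'   [feature_names()].
#' @export
build_feature_matrix <- function(streams, infants, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  per_infant <- lapply(names(streams), function(id) {
    stream <- streams[[id]]
    rec <- infants[infants$infant_id == id, ]
    if (nrow(rec) != 1) abort_ctx("no static record for infant %s", id)
    if (anyNA(stream[config$dynamic_channels])) {
      abort_ctx("stream for infant %s still has missing values; impute first", id)
    }
    if (isTRUE(rec$died)) stream <- stream[stream$t_s < rec$death_time_s, ]
    statics <- encode_statics(rec)
    cols <- list()
    for (ch in config$dynamic_channels) {
      for (w in config$window_lengths_s) {
        rs <- rolling_stats(stream[[ch]], w, config$period_s)
        for (st in config$statistics) {
          cols[[paste(ch, st, w, sep = "_")]] <- rs[[st]]
        }
      }
    }
    tibble::tibble(infant_id = id, t_s = stream$t_s,
                   !!!as.list(statics), !!!cols)
  })
  out <- dplyr::bind_rows(per_infant)
  out[, c("infant_id", "t_s", feature_names(config))]
}
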