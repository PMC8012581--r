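#' Configuration for the synthetic NICU cohort generator
#'
#' Bundles every tunable of the simulated cohort: the gestational-age (GA)
#' and birth-weight (BW) joint law, the GA/BW-dependent mortality model, the
#' vital-sign dynamics, the pre-mortem decompensation signature, artifact
#' rates, and blood-pressure sourcing. Defaults are calibrated so that a
#' large cohort reproduces the demographic profile of a very-preterm NICU
#' population: mean GA 27 completed weeks, mean BW about 929 g, a mortality
#' rate near 21 percent, and a deceased subgroup centred near 25 weeks /
#' 704 g.
#'
#' The mortality model is a per-completed-week baseline probability
#' `plogis(mort_intercept + mort_ga_slope * (ga - 27))`, multiplied by a
#' birth-weight adjustment `2 * plogis(-(bw - m(ga)) / mort_bw_tau)` where
#' `m(ga)` is the conditional BW mean. The adjustment averages to one over
#' the BW distribution, so the per-GA marginal stays at the baseline while
#' lighter infants within a GA stratum die more often.
#'
#' @param n_infants Number of infants to generate.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param ga_mu,ga_sigma Location/scale of the discretised normal GA law on
#'   22..31 completed weeks.
#' @param bw_intercept,bw_slope Conditional BW mean in grams:
#'   `bw_intercept + bw_slope * (ga - 27)`.
#' @param bw_sd Within-GA BW standard deviation (g).
#' @param bw_range Truncation interval for BW in grams.
#' @param mort_intercept,mort_ga_slope Logistic baseline of death probability
#'   against centred GA.
#' @param mort_bw_tau Scale (g) of the BW mortality adjustment.
#' @param sex_p_male Probability of male sex.
#' @param race_probs Named probabilities over `white, black, asian, unknown`.
#' @param duration_range_s Survivor record duration, uniform over this
#'   interval (seconds); default 80 h to 240 h.
#' @param death_min_s Earliest permitted death time (seconds).
#' @param decomp_lead_s Lead time before death at which the terminal
#'   decompensation epoch begins (seconds); must exceed 21,600 s so the
#'   6-h pre-death window lies wholly inside the epoch.
#' @param decomp_drift Named end-of-life shift of each channel mean
#'   (channel units); the shift ramps linearly from onset to death.
#' @param arterial_prob Probability an infant has an invasive arterial line
#'   (continuous BP); otherwise BP is sporadic non-invasive cuff data.
#' @param nibp_interval_s Two-element bounds (seconds) on the gap between
#'   successive non-invasive BP measurements; upper bound at most 43,200 s
#'   (the twice-daily clinical minimum).
#' @param missing_rate,out_of_range_rate Per-sample artifact probabilities.
#' @param ar_theta Mean-reversion rate of the AR(1) channel noise per second.
#' @param noise_sd Named per-channel innovation standard deviations.
#' @param setpoint_sd Named between-infant standard deviations of the
#'   channel set-points: each infant carries a persistent baseline offset,
#'   as real infants do, so a channel's level alone does not give away
#'   decompensation.
#' @param temp_mu,temp_ga_slope,temp_sd Admission temperature model
#'   (degrees C): mean `temp_mu - temp_ga_slope * (27 - ga)`.
#' @param be_mu,be_ga_slope,be_sd Admission base excess model (mmol/L):
#'   mean `be_mu - be_ga_slope * (27 - ga)`. Both feed only the CRIB-II
#'   baseline, not the classifier.
#' @return A validated list of class `generator_config`.
#' @seealso [generate_cohort()], [simulate_vitals()], [inject_artifacts()]
#' @export
generator_config <- function(n_infants = 275,
                             seed = 1L,
                             ga_mu = 27.35,
                             ga_sigma = 2.4,
                             bw_intercept = 903,
                             bw_slope = 120,
                             bw_sd = 152,
                             bw_range = c(360, 1520),
                             mort_intercept = -1.62,
                             mort_ga_slope = -0.72,
                             mort_bw_tau = 260,
                             sex_p_male = 0.5055,
                             race_probs = c(white = 0.5491, black = 0.40,
                                            asian = 0.0109, unknown = 0.04),
                             duration_range_s = c(288000, 864000),
                             death_min_s = 86400,
                             decomp_lead_s = 43200,
                             decomp_drift = c(HR = -20, RR = -12, SPO2 = -8,
                                              BP_S = -10, BP_M = -8, BP_D = -6),
                             arterial_prob = 0.4,
                             nibp_interval_s = c(1800, 43200),
                             missing_rate = 0.02,
                             out_of_range_rate = 0.005,
                             ar_theta = 0.01,
                             noise_sd = c(HR = 2.0, RR = 1.5, SPO2 = 0.5,
                                          BP_S = 0.8, BP_M = 0.7, BP_D = 0.6),
                             setpoint_sd = c(HR = 14, RR = 8, SPO2 = 3,
                                             BP_S = 5, BP_M = 4, BP_D = 4),
                             temp_mu = 36.5, temp_ga_slope = 0.2, temp_sd = 0.6,
                             be_mu = -4, be_ga_slope = 0.7, be_sd = 3) {
  if (!is.numeric(n_infants) || length(n_infants) != 1 || n_infants < 1) {
    abort_ctx("`n_infants` must be a positive integer (got %s)", n_infants)
  }
  assert_prob(sex_p_male, "sex_p_male")
  assert_prob(arterial_prob, "arterial_prob")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(out_of_range_rate, "out_of_range_rate")
  assert_prob(race_probs, "race_probs")
  if (!setequal(names(race_probs), RACE_LEVELS)) {
    abort_ctx("`race_probs` must be named with exactly: %s",
              paste(RACE_LEVELS, collapse = ", "))
  }
  if (abs(sum(race_probs) - 1) > 1e-8) abort_ctx("`race_probs` must sum to 1")
  if (nibp_interval_s[2] > 43200) {
    abort_ctx("NIBP interval upper bound must be <= 43200 s")
  }
  if (nibp_interval_s[1] <= 0 || nibp_interval_s[1] > nibp_interval_s[2]) {
    abort_ctx("`nibp_interval_s` must be increasing positive bounds")
  }
  if (decomp_lead_s <= 21600) {
    abort_ctx("`decomp_lead_s` must exceed 21600 s so the worry window sits inside the decompensation epoch")
  }
  if (duration_range_s[1] <= 0 || duration_range_s[1] > duration_range_s[2]) {
    abort_ctx("`duration_range_s` must be increasing positive bounds")
  }
  stopifnot(setequal(names(decomp_drift), VITAL_CHANNELS),
            setequal(names(noise_sd), VITAL_CHANNELS),
            setequal(names(setpoint_sd), VITAL_CHANNELS),
            bw_range[1] < bw_range[2], ga_sigma > 0, bw_sd > 0,
            mort_bw_tau > 0, ar_theta > 0, ar_theta < 1,
            death_min_s > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  n_infants: %d   seed: %d\n", as.integer(x$n_infants), as.integer(x$seed)))
  cat(sprintf("  GA ~ discretised N(%.2f, %.2f) on 22..31 wk; BW mean %g %+g g/wk, sd %g g\n",
              x$ga_mu, x$ga_sigma, x$bw_intercept, x$bw_slope, x$bw_sd))
  cat(sprintf("  mortality: plogis(%.2f %+.2f (GA-27)) x BW adjustment (tau = %g g)\n",
              x$mort_intercept, x$mort_ga_slope, x$mort_bw_tau))
  cat(sprintf("  decompensation lead %g h; artifacts: %.1f%% missing, %.2f%% out-of-range\n",
              x$decomp_lead_s / 3600, 100 * x$missing_rate, 100 * x$out_of_range_rate))
  invisible(x)
}

# Probability mass of GA over 22..31 completed weeks.
ga_pmf <- function(config) {
  w <- stats::dnorm(22:31, config$ga_mu, config$ga_sigma)
  w / sum(w)
}

# Conditional BW mean in grams given completed weeks.
bw_mean_for_ga <- function(config, ga) config$bw_intercept + config$bw_slope * (ga - 27)

# Death probability given GA and BW (before capping the cohort draw).
death_probability <- function(config, ga, bw) {
  base <- stats::plogis(config$mort_intercept + config$mort_ga_slope * (ga - 27))
  adj <- 2 * stats::plogis(-(bw - bw_mean_for_ga(config, ga)) / config$mort_bw_tau)
  pmin(1, base * adj)
}

#' Closed-form marginal mortality of the generator
#'
#' Integrates the death model over the truncated-normal BW law within each
#' GA stratum and sums against the GA mass function. Used as the
#' independent reference the empirical death fraction of large simulated
#' cohorts must match.
#'
#' @param config A [generator_config()].
#' @return Scalar marginal death probability.
#' @export
marginal_mortality <- function(config) {
  pmf <- ga_pmf(config)
  lo <- config$bw_range[1]; hi <- config$bw_range[2]
  per_ga <- vapply(22:31, function(ga) {
    m <- bw_mean_for_ga(config, ga)
    z <- stats::pnorm(hi, m, config$bw_sd) - stats::pnorm(lo, m, config$bw_sd)
    stats::integrate(function(bw) {
      death_probability(config, ga, bw) * stats::dnorm(bw, m, config$bw_sd) / z
    }, lo, hi, rel.tol = 1e-9)$value
  }, numeric(1))
  sum(pmf * per_ga)
}

#' Generate a synthetic NICU cohort
#'
#' Draws `config$n_infants` infant records: gestational age on 22..31
#' completed weeks, birth weight from a GA-conditional truncated normal on
#' [360, 1520] g, sex/race from fixed marginals, death from the GA/BW
#' mortality model, plus the admission covariates (temperature, base
#' excess) consumed by the CRIB-II baseline. Record durations are uniform;
#' a deceased infant's record ends at the death time, which is uniform over
#' `[death_min_s, drawn duration]` and snapped to the 10-s analysis grid.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per infant: `infant_id`, `ga_weeks`,
#'   `birth_weight_g`, `sex`, `race`, `died`, `death_time_s` (`NA` for
#'   survivors), `record_duration_s`, `bp_source`, `admission_temp_c`,
#'   `base_excess_mmol_l`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_infants = 20, seed = 42))
#' table(cohort$died)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n_infants)
  with_seed(derive_seed(config$seed, "cohort"), {
    ga <- sample(22:31, n, replace = TRUE, prob = ga_pmf(config))
    m <- bw_mean_for_ga(config, ga)
    bw <- stats::rnorm(n, m, config$bw_sd)
    bad <- bw < config$bw_range[1] | bw > config$bw_range[2]
    while (any(bad)) {  # rejection sampling keeps the conditional law normal
      bw[bad] <- stats::rnorm(sum(bad), m[bad], config$bw_sd)
      bad <- bw < config$bw_range[1] | bw > config$bw_range[2]
    }
    bw <- round(bw)
    sex <- ifelse(stats::runif(n) < config$sex_p_male, "male", "female")
    race <- sample(RACE_LEVELS, n, replace = TRUE,
                   prob = config$race_probs[RACE_LEVELS])
    died <- stats::runif(n) < death_probability(config, ga, bw)
    dur <- round(stats::runif(n, config$duration_range_s[1],
                              config$duration_range_s[2]) / 10) * 10
    death_time <- rep(NA_real_, n)
    if (any(died)) {
      lo <- pmin(config$death_min_s, dur[died])
      death_time[died] <- round(stats::runif(sum(died), lo, dur[died]) / 10) * 10
      dur[died] <- death_time[died]
    }
    temp <- stats::rnorm(n, config$temp_mu - config$temp_ga_slope * (27 - ga),
                         config$temp_sd)
    be <- stats::rnorm(n, config$be_mu - config$be_ga_slope * (27 - ga),
                       config$be_sd)
    tibble::tibble(
      infant_id = sprintf("P%05d", seq_len(n)),
      ga_weeks = as.integer(ga),
      birth_weight_g = bw,
      sex = sex,
      race = race,
      died = died,
      death_time_s = death_time,
      record_duration_s = dur,
      bp_source = ifelse(stats::runif(n) < config$arterial_prob,
                         "arterial", "non_invasive"),
      admission_temp_c = round(temp, 1),
      base_excess_mmol_l = round(be, 1)
    )
  })
}

# GA-dependent channel set-points. The mean arterial pressure set-point
# follows the clinical rule of thumb MAP (mmHg) ~= GA (weeks).
channel_setpoints <- function(ga) {
  c(HR = 165 - 1.5 * (ga - 27), RR = 50, SPO2 = 93,
    BP_S = ga + 10, BP_M = ga, BP_D = ga - 7)
}

#' Simulate a 1-Hz vital-sign stream for one infant
#'
#' Each channel is mean-reverting AR(1) noise around a GA-dependent
#' set-point, sampled at 1 Hz on `t = 0 .. record_duration_s`. For deceased
#' infants the record ends at the death time and the final decompensation
#' epoch ramps the channel means linearly by `config$decomp_drift` (e.g.
#' bradycardia, hypotension, desaturation) starting `decomp_lead_s` before
#' death. Non-invasive BP infants get sporadic cuff measurements (gap
#' uniform within `config$nibp_interval_s`, never more than 12 h) held at
#' the last observation between samples; arterial-line BP is continuous.
#'
#' @param infant One-row cohort tibble (see [generate_cohort()]).
#' @param config A [generator_config()].
#' @return A tibble with columns `t_s` and the six channels
#'   `HR, RR, SPO2, BP_S, BP_M, BP_D`, carrying attributes `infant_id` and
#'   `bp_source`.
#' @export
simulate_vitals <- function(infant, config) {
  stopifnot(inherits(config, "generator_config"), nrow(infant) == 1)
  if (isTRUE(infant$died) && !is.finite(infant$death_time_s)) {
    abort_ctx("deceased infant %s has no death_time_s", infant$infant_id)
  }
  dur <- infant$record_duration_s
  n <- as.integer(dur) + 1L
  t <- seq.int(0L, as.integer(dur))
  setp <- channel_setpoints(infant$ga_weeks)
  phi <- 1 - config$ar_theta
  died <- isTRUE(infant$died)
  if (died) {
    onset <- max(0, infant$death_time_s - config$decomp_lead_s)
    ramp <- pmax(0, (t - onset) / (infant$death_time_s - onset))
  }
  with_seed(derive_seed(config$seed, paste0("vitals/", infant$infant_id)), {
    offsets <- stats::rnorm(length(VITAL_CHANNELS)) *
      config$setpoint_sd[VITAL_CHANNELS]
    names(offsets) <- VITAL_CHANNELS
    cols <- lapply(VITAL_CHANNELS, function(ch) {
      sd_innov <- config$noise_sd[[ch]]
      e0 <- stats::rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
      e <- as.numeric(stats::filter(stats::rnorm(n, 0, sd_innov), phi,
                                    method = "recursive", init = e0))
      mu <- rep(setp[[ch]] + offsets[[ch]], n)
      if (died) mu <- mu + ramp * config$decomp_drift[[ch]]
      x <- mu + e
      if (ch == "SPO2") x <- pmin(x, 100)
      pmax(x, 0)
    })
    names(cols) <- VITAL_CHANNELS
    if (identical(infant$bp_source, "non_invasive")) {
      gaps <- stats::runif(ceiling(dur / config$nibp_interval_s[1]) + 1L,
                           config$nibp_interval_s[1], config$nibp_interval_s[2])
      times <- unique(pmin(round(c(0, cumsum(gaps))), dur))
      times <- times[times <= dur]
      idx <- findInterval(t, times)  # hold last cuff observation
      for (ch in c("BP_S", "BP_M", "BP_D")) {
        cols[[ch]] <- cols[[ch]][times + 1L][idx]
      }
    }
    out <- tibble::tibble(t_s = as.numeric(t), !!!cols)
    attr(out, "infant_id") <- infant$infant_id
    attr(out, "bp_source") <- infant$bp_source
    out
  })
}

#' Corrupt a vital-sign stream with missing and out-of-range artifacts
#'
#' Emulates the dropouts and physically impossible readings of bedside
#' monitor archives: for every channel a fraction `missing_rate` of samples
#' becomes `NA` and a fraction `out_of_range_rate` is replaced by a value
#' outside the channel's viable range (below the lower or above the upper
#' bound, chosen at random). Sample positions are drawn without
#' replacement, so each sample's marginal corruption probability equals the
#' configured rate. With both rates zero the stream is returned unchanged.
#'
#' @param stream Output of [simulate_vitals()].
#' @param config A [generator_config()].
#' @return The corrupted stream (same shape and attributes).
#' @export
inject_artifacts <- function(stream, config) {
  stopifnot(inherits(config, "generator_config"))
  assert_prob(config$missing_rate, "missing_rate")
  assert_prob(config$out_of_range_rate, "out_of_range_rate")
  if (config$missing_rate == 0 && config$out_of_range_rate == 0) return(stream)
  id <- attr(stream, "infant_id") %||% "stream"
  ranges <- viable_ranges()
  n <- nrow(stream)
  with_seed(derive_seed(config$seed, paste0("artifacts/", id)), {
    for (ch in VITAL_CHANNELS) {
      k_miss <- stats::rbinom(1, n, config$missing_rate)
      k_oor <- stats::rbinom(1, n, config$out_of_range_rate)
      if (k_miss + k_oor == 0) next
      idx <- sample.int(n, min(n, k_miss + k_oor))
      x <- stream[[ch]]
      if (k_miss > 0) x[idx[seq_len(k_miss)]] <- NA_real_
      if (k_oor > 0 && k_miss < length(idx)) {
        oor_idx <- idx[(k_miss + 1L):length(idx)]
        r <- ranges[[ch]]
        high <- stats::runif(length(oor_idx)) < 0.5
        x[oor_idx] <- ifelse(high,
                             r[2] + stats::runif(length(oor_idx), 1, 50),
                             r[1] - stats::runif(length(oor_idx), 1, 50))
      }
      stream[[ch]] <- x
    }
    stream
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
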