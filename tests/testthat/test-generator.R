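test_that("cohorts have the requested size, valid fields, and are seeded", {
  cfg <- generator_config(n_infants = 275, seed = 3)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 275)
  expect_true(all(cohort$ga_weeks >= 22 & cohort$ga_weeks <= 31))
  expect_true(all(cohort$birth_weight_g >= 360 & cohort$birth_weight_g <= 1520))
  expect_true(all(cohort$sex %in% c("male", "female")))
  expect_true(all(cohort$race %in% c("white", "black", "asian", "unknown")))
  dead <- cohort[cohort$died, ]
  expect_true(all(is.finite(dead$death_time_s)))
  expect_true(all(dead$death_time_s <= dead$record_duration_s))
  expect_true(all(is.na(cohort$death_time_s[!cohort$died])))
  # identical config + seed => byte-identical cohort
  expect_identical(cohort, generate_cohort(generator_config(n_infants = 275, seed = 3)))
  # different seed => different draw
  expect_false(identical(cohort$birth_weight_g,
                         generate_cohort(generator_config(n_infants = 275, seed = 4))$birth_weight_g))
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(n_infants = 0), "positive")
  expect_error(generator_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(nibp_interval_s = c(1800, 50000)), "43200")
  expect_error(generator_config(decomp_lead_s = 21600), "21600")
  expect_error(generator_config(race_probs = c(white = 0.5, black = 0.5,
                                               asian = 0, unknown = 0.1)), "sum to 1")
})

test_that("empirical death fraction matches the closed-form marginal", {
  cfg <- generator_config(n_infants = 50000, seed = 11)
  cohort <- generate_cohort(cfg)
  p <- marginal_mortality(cfg)
  se <- sqrt(p * (1 - p) / nrow(cohort))
  expect_lt(abs(mean(cohort$died) - p), 3 * se)
})

test_that("configured and empirical death risk decrease with gestational age", {
  cfg <- generator_config(n_infants = 100000, seed = 5)
  # configured baseline is non-increasing in GA at the conditional BW mean
  base <- vapply(22:31, function(g)
    neoworry:::death_probability(cfg, g, neoworry:::bw_mean_for_ga(cfg, g)),
    numeric(1))
  expect_true(all(diff(base) <= 0))
  # empirical per-GA rates preserve the ordering up to Monte-Carlo noise
  cohort <- generate_cohort(cfg)
  rates <- tapply(cohort$died, cohort$ga_weeks, mean)
  ns <- tapply(cohort$died, cohort$ga_weeks, length)
  for (i in seq_len(length(rates) - 1)) {
    se_diff <- sqrt(rates[i] * (1 - rates[i]) / ns[i] +
                      rates[i + 1] * (1 - rates[i + 1]) / ns[i + 1])
    expect_lt(rates[i + 1] - rates[i], 3 * se_diff + 1e-12)
  }
  # deceased infants are lighter on average
  expect_lt(mean(cohort$birth_weight_g[cohort$died]),
            mean(cohort$birth_weight_g[!cohort$died]))
})

test_that("vital streams honour the length, decompensation, and NIBP contracts", {
  cfg <- small_gen_config()
  surv <- make_infant(duration = 288000)
  s <- simulate_vitals(surv, cfg)
  expect_equal(nrow(s), 288001)
  expect_identical(s$t_s[1:3], c(0, 1, 2))
  # determinism
  expect_identical(s, simulate_vitals(surv, cfg))

  dead <- make_infant(id = "P00002", died = TRUE, death_time = 172800,
                      duration = 172800)
  sd_ <- simulate_vitals(dead, cfg)
  expect_equal(max(sd_$t_s), 172800)
  # last pre-death hour sits below the first recorded hour by roughly the
  # configured drift (noise is mean-reverting with small stationary sd)
  first_hr <- mean(sd_$HR[sd_$t_s < 3600])
  last_hr <- mean(sd_$HR[sd_$t_s >= 172800 - 3600])
  expect_lt(last_hr, first_hr)
  expect_lt(abs((first_hr - last_hr) - abs(cfg$decomp_drift[["HR"]])), 10)

  # survivors carry no decompensation epoch: first/last-hour means agree
  # within the process noise
  expect_lt(abs(mean(s$HR[s$t_s < 3600]) - mean(s$HR[s$t_s >= 288000 - 3600])), 10)

  nibp <- make_infant(id = "P00003", bp_source = "non_invasive", duration = 288000)
  sn <- simulate_vitals(nibp, cfg)
  updates <- sum(diff(sn$BP_M) != 0) + 1
  expect_gte(updates, 288000 / 43200)
  # held between cuff samples: few distinct values relative to samples
  expect_lt(length(unique(sn$BP_M)), 500)
  # gaps between cuff updates never exceed twelve hours
  update_times <- sn$t_s[c(TRUE, diff(sn$BP_M) != 0)]
  expect_true(all(diff(update_times) <= 43200))
})

test_that("artifact injection hits configured rates and respects ranges", {
  cfg <- small_gen_config(missing_rate = 0.05, out_of_range_rate = 0.01)
  inf <- make_infant(duration = 99999)  # 100,000 samples
  s <- simulate_vitals(inf, cfg)
  corrupted <- inject_artifacts(s, cfg)
  n <- nrow(corrupted)
  miss <- sum(is.na(corrupted$HR))
  expect_lt(abs(miss - n * 0.05), 3 * sqrt(n * 0.05 * 0.95))
  r <- viable_ranges()
  oor <- sum(!is.na(corrupted$SPO2) &
               (corrupted$SPO2 < r$SPO2[1] | corrupted$SPO2 > r$SPO2[2]))
  expect_lt(abs(oor - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
  # injected out-of-range SpO2 values are only > 100 or < 0
  bad <- corrupted$SPO2[!is.na(corrupted$SPO2)]
  bad <- bad[bad < r$SPO2[1] | bad > r$SPO2[2]]
  expect_true(all(bad > 100 | bad < 0))
  # zero rates leave the stream untouched
  cfg0 <- small_gen_config(missing_rate = 0, out_of_range_rate = 0)
  expect_identical(inject_artifacts(s, cfg0), s)
  # seeded: same stream + config twice gives identical corruption
  expect_identical(corrupted, inject_artifacts(s, cfg))
})

test_that("large cohorts reproduce the calibrated demographic profile", {
  cohort <- cached("calib_cohort",
                   generate_cohort(generator_config(n_infants = 10000, seed = 2)))
  expect_lt(abs(mean(cohort$ga_weeks) - 27), 0.5)
  expect_lt(abs(mean(cohort$birth_weight_g) - 929), 45)
  expect_lt(abs(mean(cohort$birth_weight_g[cohort$died]) - 704), 45)
  expect_lt(abs(mean(cohort$died) - 0.2145), 0.02)
  expect_lt(abs(mean(cohort$ga_weeks[cohort$died]) - 25), 0.7)
})
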