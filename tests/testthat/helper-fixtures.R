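# Shared fixture builders. Everything is generated in code at test time.

# A small generator configuration with short (just-included) records so
# end-to-end fixtures stay fast; scientific defaults are untouched.
small_gen_config <- function(n = 30, seed = 7, ...) {
  generator_config(n_infants = n, seed = seed,
                   duration_range_s = c(288000, 302400),
                   death_min_s = 288000, ...)
}

# A minimal one-infant cohort row without simulating vitals.
make_infant <- function(id = "P00001", ga = 27, bw = 900, sex = "female",
                        race = "white", died = FALSE, death_time = NA_real_,
                        duration = 288000, bp_source = "arterial") {
  tibble::tibble(infant_id = id, ga_weeks = as.integer(ga),
                 birth_weight_g = bw, sex = sex, race = race, died = died,
                 death_time_s = death_time, record_duration_s = duration,
                 bp_source = bp_source, admission_temp_c = 36.5,
                 base_excess_mmol_l = -4)
}

# A bare (infant_id, t_s) grid masquerading as a feature matrix, for
# labeling arithmetic that does not need real features.
make_grid_matrix <- function(ids, durations, period = 10) {
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    tibble::tibble(infant_id = ids[i],
                   t_s = seq(0, durations[i] - period, by = period),
                   x = 0)
  }))
}

# A small labeled dataset with a learnable rule, for classifier tests.
make_toy_dataset <- function(n_infants = 10, rows_per_infant = 60, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_infants), function(i) {
      hr <- rnorm(rows_per_infant, mean = ifelse(i %% 2 == 0, 120, 70), sd = 5)
      tibble::tibble(infant_id = sprintf("T%03d", i),
                     t_s = seq(0, by = 10, length.out = rows_per_infant),
                     HR_mean_300 = hr,
                     noise = rnorm(rows_per_infant),
                     label = as.integer(hr < 80))
    }))
  })
}

# Brute-force trailing-window statistics used as the rolling oracle.
brute_rolling <- function(x, w) {
  n <- length(x)
  out <- list(mean = numeric(n), sd = numeric(n), absz = numeric(n))
  for (i in seq_len(n)) {
    win <- x[max(1, i - w + 1):i]
    out$mean[i] <- mean(win)
    out$sd[i] <- if (length(win) >= 2) stats::sd(win) else 0
    out$absz[i] <- if (out$sd[i] > 0) abs(x[i] - out$mean[i]) / out$sd[i] else 0
  }
  out
}

# O(n^2) pairwise concordance AUC oracle (ties count one half).
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Memoised cache for expensive cross-test fixtures.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A cached n=30 end-to-end run shared by the pipeline smoke tests and the
# reproducibility check.
smoke_run <- function(key) {
  cached(key, {
    out_dir <- if (key == "smoke1") file.path(tempdir(), "neoworry-smoke1") else NULL
    gen <- small_gen_config(n = 30, seed = 1)
    # at 22 training infants the static factors can separate the few deaths,
    # so the logistic baseline legitimately warns and falls back to ridge
    res <- suppressWarnings(
      run_pipeline(pipeline_config(seed = 1, generator = gen),
                   out_dir = out_dir, quiet = TRUE))
    res$out_dir <- out_dir
    res
  })
}

# The five seeded end-to-end runs shared by the model-ordering and
# feature-importance checks: per-infant AUCs and importance ranks.
ordering_runs <- function() {
  cached("ordering_runs", {
    lapply(1:5, function(i) {
      sd <- 100 + i
      gen <- generator_config(n_infants = 80, seed = sd,
                              duration_range_s = c(288000, 316800),
                              death_min_s = 288000)
      res <- run_pipeline(pipeline_config(seed = sd, generator = gen),
                          quiet = TRUE)
      imp <- sort(res$model$importance, decreasing = TRUE)
      out <- list(
        rf_auc = res$metrics$auc[res$metrics$model == "random_forest" &
                                   res$metrics$granularity == "per_infant"],
        logistic_auc = res$metrics$auc[res$metrics$model == "logistic"],
        pt_accuracy = res$metrics$accuracy[res$metrics$granularity == "per_timepoint"],
        rank_ga = which(names(imp) == "ga_weeks"),
        rank_bw = which(names(imp) == "birth_weight_g"),
        counts = res$counts)
      rm(res); gc(verbose = FALSE)
      out
    })
  })
}
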