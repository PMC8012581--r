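#' Load the packaged CRIB-II scoring table
#'
#' CRIB-II (Clinical Risk Index for Babies II) scores an infant at
#' admission from five items folded into three components: a combined
#' gestation / birth-weight / sex subscore (0-15), admission temperature
#' (0-5), and worst base excess (0-7), for a total of 0-27. The original
#' published item table cannot be redistributed here, so the package ships
#' a synthetic stand-in (`inst/extdata/crib2_synthetic_*.csv`) with the
#' published structure, component maxima, and risk directions (lower
#' gestation, lower weight, male sex, hypothermia, and metabolic acidosis
#' all score higher). Swap in the published cells via `dir` for clinical
#' use. An MD5 checksum of the files is recorded on the returned object
#' and reported at load.
#'
#' @param dir Directory holding the three component CSVs; defaults to the
#'   packaged synthetic table.
#' @param quiet Suppress the checksum message.
#' @return List of class `crib2_table` with components `gws` (gestation /
#'   weight / sex), `temperature`, `base_excess`, and `checksum`.
#' @export
load_crib2_table <- function(dir = NULL, quiet = FALSE) {
  if (is.null(dir)) dir <- system.file("extdata", package = "neoworry")
  paths <- file.path(dir, paste0("crib2_synthetic_",
                                 c("gestation_weight_sex", "temperature", "base_excess"),
                                 ".csv"))
  if (!all(file.exists(paths))) {
    abort_ctx("CRIB-II table files not found under %s", dir)
  }
  tabs <- lapply(paths, function(p) {
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  checksum <- unname(tools::md5sum(sort(paths)))
  if (!quiet) message("CRIB-II table checksum: ", paste(substr(checksum, 1, 8), collapse = "/"))
  structure(list(gws = tabs[[1]], temperature = tabs[[2]],
                 base_excess = tabs[[3]],
                 checksum = paste(checksum, collapse = ",")),
            class = "crib2_table")
}

lookup_band <- function(x, lo, hi, points, what) {
  idx <- findInterval(x, lo)
  bad <- idx == 0 | x > hi[length(hi)]
  if (any(bad)) {
    abort_ctx("%s value(s) outside the CRIB-II table coverage: %s",
              what, paste(unique(x[bad]), collapse = ", "))
  }
  points[idx]
}

#' Compute CRIB-II scores
#'
#' Deterministic lookup-sum over the three table components. Inputs
#' outside the table's coverage raise an error; nothing is clamped.
#'
#' @param ga_weeks Completed weeks of gestation.
#' @param birth_weight_g Birth weight in grams.
#' @param sex `"male"` or `"female"`.
#' @param admission_temp_c Admission temperature, degrees Celsius.
#' @param base_excess_mmol_l Worst base excess in the first hour, mmol/L.
#' @param table A [load_crib2_table()] object.
#' @return Tibble with per-component subtotals (`gws_points`,
#'   `temp_points`, `be_points`) and their sum `total` (0-27).
#' @export
crib2_score <- function(ga_weeks, birth_weight_g, sex,
                        admission_temp_c, base_excess_mmol_l,
                        table = load_crib2_table(quiet = TRUE)) {
  stopifnot(inherits(table, "crib2_table"))
  n <- length(ga_weeks)
  if (!all(sex %in% SEX_LEVELS)) abort_ctx("sex must be one of: %s", paste(SEX_LEVELS, collapse = ", "))
  gws <- table$gws
  gws_points <- vapply(seq_len(n), function(i) {
    hit <- gws$sex == sex[i] & gws$ga_weeks == ga_weeks[i] &
      gws$bw_lo <= birth_weight_g[i] & birth_weight_g[i] < gws$bw_hi
    if (sum(hit) != 1) {
      abort_ctx("gestation %s wk / weight %s g outside the CRIB-II table coverage",
                ga_weeks[i], birth_weight_g[i])
    }
    as.numeric(gws$points[hit])
  }, numeric(1))
  temp_points <- lookup_band(admission_temp_c, table$temperature$temp_lo,
                             table$temperature$temp_hi, table$temperature$points,
                             "admission temperature")
  be_points <- lookup_band(base_excess_mmol_l, table$base_excess$be_lo,
                           table$base_excess$be_hi, table$base_excess$points,
                           "base excess")
  tibble::tibble(gws_points = gws_points, temp_points = temp_points,
                 be_points = be_points,
                 total = gws_points + temp_points + be_points)
}

#' Enumerate the maximum achievable CRIB-II total
#'
#' Sweeps every combination of gestation/weight/sex cell, temperature
#' band, and base-excess band in the packaged table and returns the
#' largest total.
#'
#' @param table A [load_crib2_table()] object.
#' @return Integer maximum total.
#' @export
crib2_max_total <- function(table = load_crib2_table(quiet = TRUE)) {
  totals <- outer(outer(table$gws$points, table$temperature$points, `+`),
                  table$base_excess$points, `+`)
  max(totals)
}

#' Threshold a CRIB-II total into a worry flag
#'
#' Scores at or beyond the threshold (default 11, the level associated
#' with mortality) are flagged worry.
#'
#' @param total CRIB-II total score(s).
#' @param threshold Worry threshold.
#' @return Integer worry flag(s), 1 = worry.
#' @export
crib2_classify <- function(total, threshold = 11) {
  as.integer(total >= threshold)
}

#' Static-only logistic regression baseline
#'
#' Fits a maximum-likelihood logistic regression of the eventual-death
#' outcome on the four encoded static factors, yielding one worry
#' probability per infant. Under perfect separation the ML fit diverges; a
#' warning is issued and a weakly ridge-penalised fit (glmnet, alpha = 0)
#' is used instead.
#'
#' @param statics Tibble with columns `ga_weeks`, `sex_code`, `race_code`,
#'   `birth_weight_g` (see [encode_statics()]).
#' @param died Logical (or 0/1) outcome per infant.
#' @return Object of class `logistic_baseline` with `coefficients` and a
#'   `predict()` method returning probabilities.
#' @export
fit_logistic_baseline <- function(statics, died) {
  died <- as.integer(died)
  feats <- c("ga_weeks", "sex_code", "race_code", "birth_weight_g")
  stopifnot(all(feats %in% names(statics)), length(died) == nrow(statics))
  if (length(unique(died)) < 2) abort_ctx("outcomes are single-class; cannot fit the baseline")
  if (min(table(died)) < 2) abort_ctx("need at least 2 infants per outcome class")
  df <- as.data.frame(statics[, feats])
  df$died <- died
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(died ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # separation can also drive fitted values to the boundary without a
  # glm.fit warning
  if (!separated) {
    separated <- any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)
  }
  if (separated) {
    warning("perfect separation detected; falling back to a ridge-penalised fit")
    x <- as.matrix(df[, feats])
    pen <- glmnet::glmnet(x, died, family = "binomial", alpha = 0, lambda = 1e-3)
    coefs <- stats::setNames(as.numeric(stats::coef(pen)), rownames(stats::coef(pen)))
    obj <- list(kind = "logistic_ridge", fit = pen, coefficients = coefs,
                feature_names = feats)
  } else {
    obj <- list(kind = "logistic", fit = fit, coefficients = stats::coef(fit),
                feature_names = feats)
  }
  structure(obj, class = "logistic_baseline")
}

#' @export
predict.logistic_baseline <- function(object, newdata, ...) {
  df <- as.data.frame(newdata[, object$feature_names])
  if (object$kind == "logistic") {
    as.numeric(stats::predict(object$fit, newdata = df, type = "response"))
  } else {
    as.numeric(stats::predict(object$fit, newx = as.matrix(df), type = "response"))
  }
}

#' @export
print.logistic_baseline <- function(x, ...) {
  cat(sprintf("<logistic_baseline> (%s)\n", x$kind))
  print(round(x$coefficients, 5))
  invisible(x)
}
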