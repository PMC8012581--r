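COHORT_COLUMNS <- c("infant_id", "ga_weeks", "birth_weight_g", "sex", "race",
                    "died", "death_time_s", "record_duration_s")
COHORT_OPTIONAL <- c("bp_source", "admission_temp_c", "base_excess_mmol_l")

#' Write / read the cohort CSV dialect
#'
#' Header `infant_id,ga_weeks,birth_weight_g,sex,race,died,death_time_s,
#' record_duration_s`, optionally followed by `bp_source`,
#' `admission_temp_c`, `base_excess_mmol_l`. A survivor's `death_time_s`
#' is empty. Reading is strict: missing or unrecognised columns fail.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  keep <- intersect(c(COHORT_COLUMNS, COHORT_OPTIONAL), names(cohort))
  readr::write_csv(cohort[, keep], path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(COHORT_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort_ctx("cohort file %s lacks column(s): %s", path,
              paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(header, c(COHORT_COLUMNS, COHORT_OPTIONAL))
  if (length(unknown) > 0) {
    abort_ctx("cohort file %s has unrecognised column(s): %s", path,
              paste(unknown, collapse = ", "))
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    infant_id = "c", ga_weeks = "i", birth_weight_g = "d", sex = "c",
    race = "c", died = "l", death_time_s = "d", record_duration_s = "d",
    .default = readr::col_guess()), na = "", progress = FALSE)
  bad_race <- setdiff(unique(x$race), RACE_LEVELS)
  if (length(bad_race) > 0) abort_ctx("unrecognised race value(s): %s", paste(bad_race, collapse = ", "))
  x
}

#' Write / read vital-sign streams as long CSV
#'
#' Dialect: header `infant_id,t_s,channel,value`; channel names exactly
#' `HR, RR, SPO2, BP_S, BP_M, BP_D`; an empty value field marks a missing
#' sample. Reading validates the channel vocabulary and strictly
#' increasing time within each infant, and returns the wide per-infant
#' stream list the rest of the package consumes.
#'
#' @param streams Named list of wide streams (see [simulate_vitals()]).
#' @param path File path.
#' @return `write_vitals_csv` returns `path` invisibly; `read_vitals_csv`
#'   a named list of streams.
#' @export
write_vitals_csv <- function(streams, path) {
  long <- lapply(names(streams), function(id) {
    s <- streams[[id]]
    tibble::tibble(
      infant_id = id,
      t_s = rep(s$t_s, length(VITAL_CHANNELS)),
      channel = rep(VITAL_CHANNELS, each = nrow(s)),
      value = unlist(s[VITAL_CHANNELS], use.names = FALSE))
  })
  readr::write_csv(dplyr::bind_rows(long), path, na = "")
  invisible(path)
}

#' @rdname write_vitals_csv
#' @export
read_vitals_csv <- function(path) {
  x <- readr::read_csv(path, col_types = "cdcd", na = "", progress = FALSE)
  if (!identical(names(x), c("infant_id", "t_s", "channel", "value"))) {
    abort_ctx("vitals file %s must have header infant_id,t_s,channel,value", path)
  }
  bad <- setdiff(unique(x$channel), VITAL_CHANNELS)
  if (length(bad) > 0) {
    abort_ctx("vitals file %s has unrecognised channel(s): %s", path,
              paste(bad, collapse = ", "))
  }
  out <- lapply(split(x, x$infant_id), function(d) {
    for (ch in unique(d$channel)) {
      t_ch <- d$t_s[d$channel == ch]
      if (any(diff(t_ch) <= 0)) {
        abort_ctx("non-monotone time grid for infant %s in %s", d$infant_id[1], path)
      }
    }
    wide <- tidyr::pivot_wider(d[, c("t_s", "channel", "value")],
                               names_from = "channel", values_from = "value")
    wide <- wide[order(wide$t_s), c("t_s", intersect(VITAL_CHANNELS, names(wide)))]
    attr(wide, "infant_id") <- d$infant_id[1]
    wide
  })
  out
}

#' Write / read a feature matrix CSV
#'
#' Columns: `infant_id`, `t_s`, the deterministic feature names of
#' [feature_names()], and (if present) `label`.
#'
#' @param matrix Feature matrix tibble.
#' @param path File path.
#' @return The path (write) or the tibble (read).
#' @export
write_features_csv <- function(matrix, path) {
  readr::write_csv(matrix, path, na = "")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    infant_id = "c", .default = "d"), na = "", progress = FALSE)
  if (!all(c("infant_id", "t_s") %in% names(x))) {
    abort_ctx("feature file %s must carry infant_id and t_s columns", path)
  }
  x
}

#' Write per-timepoint predictions to CSV
#'
#' Header `infant_id,t_s,probability,label`.
#'
#' @param predictions Output of [predict_timepoints()].
#' @param path File path.
#' @export
write_predictions_csv <- function(predictions, path) {
  readr::write_csv(predictions[, c("infant_id", "t_s", "probability", "label")],
                   path, na = "")
  invisible(path)
}

#' Write / validate the metrics JSON report
#'
#' One object per model/granularity with `model`, `granularity`,
#' `accuracy`, `sensitivity`, `specificity`, `auc`. ROC point lists are
#' emitted to a separate CSV by the pipeline.
#'
#' @param metrics Metrics tibble (see [compare_models()]).
#' @param path File path.
#' @export
write_metrics_json <- function(metrics, path) {
  objs <- lapply(seq_len(nrow(metrics)), function(i) {
    list(model = metrics$model[i], granularity = metrics$granularity[i],
         accuracy = metrics$accuracy[i], sensitivity = metrics$sensitivity[i],
         specificity = metrics$specificity[i], auc = metrics$auc[i])
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_json
#' @param x Parsed JSON (list) as read back from a metrics file.
#' @return `validate_metrics` returns `TRUE` or raises an error.
#' @export
validate_metrics <- function(x) {
  need <- c("model", "granularity", "accuracy", "sensitivity", "specificity", "auc")
  for (obj in x) {
    missing_f <- setdiff(need, names(obj))
    if (length(missing_f) > 0) {
      abort_ctx("metrics object lacks field(s): %s", paste(missing_f, collapse = ", "))
    }
    for (f in c("accuracy", "sensitivity", "specificity", "auc")) {
      v <- obj[[f]]
      if (!is.numeric(v) || v < 0 || v > 1) abort_ctx("metrics field %s must be a fraction in [0,1]", f)
    }
  }
  TRUE
}

#' Persist / restore a trained worry model
#'
#' Serialised with a format-version field so stale files are rejected on
#' load.
#'
#' @param model A `worry_model`.
#' @param path File path (`.rds`).
#' @export
save_worry_model <- function(model, path) {
  stopifnot(inherits(model, "worry_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_worry_model
#' @export
load_worry_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format_version, 1L)) {
    abort_ctx("unsupported model file version: %s", x$format_version)
  }
  x$model
}
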