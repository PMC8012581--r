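#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

# Channel vocabulary shared across the package. BP channels are systolic /
# mean / diastolic regardless of source (arterial line vs cuff).
VITAL_CHANNELS <- c("HR", "RR", "SPO2", "BP_S", "BP_M", "BP_D")

SEX_LEVELS <- c("male", "female")
RACE_LEVELS <- c("white", "black", "asian", "unknown")

abort_ctx <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_ctx("`%s` must lie in [0, 1] (got %s)", name, paste(x, collapse = ", "))
  }
  invisible(x)
}

#' Derive a reproducible sub-seed from a base seed and a string key
#'
#' One global seed deterministically derives every stage and per-infant seed,
#' so stages can be re-run independently yet reproducibly. The key is hashed
#' with a 31-ary polynomial rolling hash modulo 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param key Character scalar naming the stage or record.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key), length(key) == 1)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer((h + (abs(seed) %% m) * 10007) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
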