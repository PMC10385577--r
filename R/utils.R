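# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves rounded up, the convention
#' used throughout for crop-dimension arithmetic and table-style report
#' rounding (base [round()] rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a master seed and a string key, so each
# component of a generated scene draws from its own reproducible stream.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
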