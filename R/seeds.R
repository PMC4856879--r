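#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows through one splitting scheme so that any
#' replicate or cohort can be regenerated in isolation: a parent seed and a
#' small integer key are mixed by a multiplicative congruential step modulo the
#' Mersenne prime 2^31 - 1. Keys at the same level must be distinct; nested
#' calls (scenario -> replicate -> cohort) give distinct streams.
#'
#' @param seed parent seed, a non-negative integer below 2^31.
#' @param key integer key (replicate index, cohort index, stage tag, ...).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' seed_child(42, 1)
#' seed_child(seed_child(42, 1), 3)
seed_child <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed < 2^31)
  stopifnot(is.numeric(key), length(key) == 1, key >= 0)
  m <- 2147483647 # 2^31 - 1
  # all intermediates stay below 2^53, exact in doubles
  x <- (seed %% m) * 48271 %% m
  x <- (x + (key %% m) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}

# run expr with a local RNG state seeded at `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
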