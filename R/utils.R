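# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All seeded operations in the package go through this helper so that a call
#' never disturbs the global random-number stream. A single PRNG algorithm
#' (Mersenne-Twister, R's default) is used throughout for cross-platform
#' sequence-level determinism.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive a child seed from a user seed, kept below 2^31 (double arithmetic
# stays exact here, well inside 2^53).
child_seed <- function(seed, index) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 +
                as.numeric(index) * 31) %% 2147483647)
}

stop_mr <- function(...) stop(..., call. = FALSE)
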