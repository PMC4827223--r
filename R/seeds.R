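## Deterministic seed streams.
##
## Each (scenario, replicate) pair gets its own seed derived from the base
## seed by folding integers through a multiplicative congruential step
## (MINSTD multiplier, modulus 2^31 - 1).  All arithmetic stays below 2^53
## so it is exact in doubles, and every derived seed fits a 32-bit integer.

SEED_MOD <- 2147483647  # 2^31 - 1

seed_fold <- function(h, k) {
  ((h %% SEED_MOD) * 48271 + (k %% SEED_MOD)) %% SEED_MOD
}

#' Derive a reproducible child seed from a base seed
#'
#' Folds a base seed and up to two stream identifiers (for example a
#' scenario index and a replicate number) into a single seed in
#' `[1, 2^31 - 2]`.  Used so that every Monte-Carlo replicate draws from its
#' own named stream: replicates are reproducible individually and
#' independent of execution order.
#'
#' @param base integer base seed.
#' @param stream integer stream identifier (e.g. scenario index).
#' @param rep integer replicate number.
#' @return A single integer seed, always strictly positive.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(base, stream = 0L, rep = 0L) {
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  h <- seed_fold(17, abs(base))
  h <- seed_fold(h, stream)
  h <- seed_fold(h, rep)
  as.integer(h %% (SEED_MOD - 1L)) + 1L
}
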