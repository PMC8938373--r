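# Seed sub-stream derivation: every stochastic operation in the package
# draws from a stream derived deterministically from (master seed, label),
# so regeneration with the same master seed is bit-identical while
# distinct stages never share a stream.

#' Derive a sub-stream seed from a master seed and a label
#'
#' @param seed integer master seed.
#' @param label character stream label (e.g. "cohort", "subject3/block2").
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 1000000007
  s <- (as.numeric(seed) %% 2147483647) * 48271 + h
  as.integer(s %% 2147483646) + 1L
}

#' @keywords internal
local_seed <- function(seed, label) {
  set.seed(derive_seed(seed, label))
  invisible(NULL)
}
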