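# Seed substream derivation. Every pipeline stage draws from its own
# substream keyed by (root seed, stage name, trait index), so adding a trait
# or reordering stages never perturbs draws made by other stages.

MERSENNE31 <- 2147483647  # 2^31 - 1

hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% MERSENNE31
  h
}

#' Derive a stage-specific seed from a root seed
#'
#' Deterministic mixing of the root seed with a stage label and a trait
#' index into a 32-bit seed. Used internally so that each simulation stage
#' (causal sampling, effect draws, noise, ...) has an independent random
#' stream per trait.
#'
#' @param seed Root integer seed.
#' @param stage Character stage label.
#' @param trait 0-based trait index (default 0).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @keywords internal
#' @export
derive_seed <- function(seed, stage, trait = 0L) {
  h <- (as.numeric(seed) %% MERSENNE31) * 48271 +
    hash_string(stage) * 69621 + as.numeric(trait) * 7919 + 1
  as.integer(h %% (MERSENNE31 - 1) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
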