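# Dense-matrix oracles and fixture shorthands. The oracles use plain matrix
# algebra on the explicit 0/1 matrix, never the graph traversals, so they
# stay independent of the code paths they check.

dense_down <- function(gm, u) as.numeric(gm$values %*% u)
dense_up <- function(gm, v) as.numeric(t(gm$values) %*% v)

# dense X beta with X the pair-summed diploid matrix
dense_genetic <- function(gm, effects, trait = 0L) {
  beta <- numeric(ncol(gm$values))
  sub <- effects[effects$trait_id == trait, , drop = FALSE]
  beta[sub$mutation_id + 1L] <- sub$effect_size
  as.numeric(diploid_matrix(gm) %*% beta)
}

# dense (X - U) Sigma beta on the standardized scale
dense_genetic_std <- function(gm, effects, trait = 0L) {
  beta <- numeric(ncol(gm$values))
  sub <- effects[effects$trait_id == trait, , drop = FALSE]
  beta[sub$mutation_id + 1L] <- sub$effect_size
  f <- colMeans(gm$values)
  sigma <- sqrt(2 * f * (1 - f))
  w <- ifelse(beta != 0, beta / sigma, 0)
  X <- diploid_matrix(gm)
  as.numeric(X %*% w - sum(2 * f * w))
}

rand_gm <- function(n_ind, n_mut, seed) {
  generate_matrix(n_ind, n_mut, freq_min = 0.05, freq_max = 0.95, seed = seed)
}

# effect sizes on a dyadic grid: graph and dense sums of these are exact in
# floating point, so "equality" assertions need no tolerance
dyadic_effects <- function(ids, seed, trait = 0L) {
  set.seed(seed)
  data.frame(mutation_id = as.integer(ids), trait_id = trait,
             effect_size = sample(c(-2, -1, -0.75, -0.25, 0.25, 0.5, 1, 1.5),
                                  length(ids), replace = TRUE))
}

expect_close <- function(actual, expected, tol = 1e-10) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
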