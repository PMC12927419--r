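test_that("genetic values equal dense X beta, haploid pairs summed", {
  g <- figure_grg()
  zero <- data.frame(mutation_id = 0L, trait_id = 0L, effect_size = 0)
  gv <- genetic_values(g, zero)
  expect_identical(gv$individuals$genetic_value, c(0, 0))

  # beta(m2) = 1: individual 0 owns samples 0 and 1, one copy of m2
  eff <- data.frame(mutation_id = 2L, trait_id = 0L, effect_size = 1)
  gv <- genetic_values(g, eff)
  expect_identical(gv$individuals$genetic_value, c(1, 1))
  expect_identical(gv$samples$genetic_value, c(0, 1, 1, 0))
  # individual value is exactly the sum of its two sample values
  expect_identical(gv$individuals$genetic_value[1],
                   sum(gv$samples$genetic_value[1:2]))

  for (seed in 1:8) {
    gm <- rand_gm(7, 13, seed = seed + 300)
    g <- build_from_matrix(gm, compress = seed %% 2 == 0)
    set.seed(seed)
    eff <- data.frame(mutation_id = sort(sample(0:12, 5)), trait_id = 0L,
                      effect_size = rnorm(5))
    gv <- genetic_values(g, eff)
    expect_close(gv$individuals$genetic_value, dense_genetic(gm, eff), 1e-10)
  }
  expect_error(genetic_values(g, data.frame(mutation_id = 50L, trait_id = 0L,
                                            effect_size = 1)), "unknown")
})

test_that("standardized genetic values equal dense (X - U) Sigma beta", {
  for (seed in 1:8) {
    gm <- rand_gm(9, 14, seed = seed + 400)
    g <- build_from_matrix(gm)
    set.seed(seed)
    eff <- data.frame(mutation_id = sort(sample(0:13, 6)), trait_id = 0L,
                      effect_size = rnorm(6))
    gv <- genetic_values_standardized(g, eff)
    expect_close(gv$individuals$genetic_value, dense_genetic_std(gm, eff), 1e-10)
    # standardized columns are mean-centered, so values average to zero
    expect_lt(abs(mean(gv$individuals$genetic_value)), 1e-9)
  }

  # beta = 0 stays exactly zero
  g <- build_from_matrix(rand_gm(5, 6, seed = 409))
  gv <- genetic_values_standardized(
    g, data.frame(mutation_id = 1L, trait_id = 0L, effect_size = 0))
  expect_identical(gv$individuals$genetic_value, rep(0, 5))

  # a monomorphic causal site has sigma = 0: named division-by-zero error
  mono <- genotype_matrix(cbind(c(1L, 0L, 1L, 0L), 1L))
  gmono <- build_from_matrix(mono)
  expect_error(genetic_values_standardized(
    gmono, data.frame(mutation_id = 1L, trait_id = 0L, effect_size = 1)),
    "mutation 1 is monomorphic")
})

test_that("noise variance is calibrated to the target heritability", {
  gm <- rand_gm(500, 50, seed = 501)
  g <- build_from_matrix(gm)
  eff <- draw_effects_standardized(0.5, sample_causal_mutations(g, 20, seed = 1),
                                   seed = 2)
  gv <- genetic_values_standardized(g, eff)

  # h2 = 1: exactly zero noise
  n0 <- environmental_noise(gv, h2 = 1, seed = 3)
  expect_identical(n0$environmental_noise, rep(0, 500))

  # Monte-Carlo: Var(eps) / V targets (1/h2 - 1)
  V <- var(gv$individuals$genetic_value)
  for (h2 in c(0.5, 0.8)) {
    ratio <- vapply(1:200, function(i) {
      eps <- environmental_noise(gv, h2 = h2, seed = 1000 + i)$environmental_noise
      var(eps) / V
    }, numeric(1))
    target <- 1 / h2 - 1
    se <- sd(ratio) / sqrt(200)
    expect_lt(abs(mean(ratio) - target), 3 * se)
  }

  expect_error(environmental_noise(gv, h2 = 0), "0, 1")
  expect_error(environmental_noise(gv, h2 = 0.5, spec = dist_spec("normal")),
               "exactly one")

  # degenerate genetic values cannot be scaled to h2 < 1
  flat <- gv
  flat$individuals$genetic_value <- rep(1, 500)
  expect_error(environmental_noise(flat, h2 = 0.5), "constant")

  # user-defined noise distribution path
  spec_noise <- environmental_noise(gv, spec = dist_spec("fixed", value = 2),
                                    seed = 4)
  expect_identical(spec_noise$environmental_noise, rep(2, 500))
})

test_that("phenotype assembly is exact addition", {
  g <- build_from_matrix(rand_gm(6, 8, seed = 601))
  eff <- dyadic_effects(c(0L, 2L, 5L), seed = 602)
  gv <- genetic_values(g, eff)
  noise <- environmental_noise(gv, h2 = 1)
  ph <- assemble_phenotypes(gv, noise)
  expect_identical(ph$phenotype, ph$genetic_value)          # zero noise
  noise$environmental_noise <- seq(0.1, 0.6, by = 0.1)
  ph <- assemble_phenotypes(gv, noise)
  expect_identical(ph$phenotype, ph$genetic_value + noise$environmental_noise)
})

test_that("standard normalization gives mean 0 sd 1; quantile matches closed form", {
  ph <- data.frame(individual_id = paste0("i", 1:20), trait_id = 0L,
                   genetic_value = rnorm(20), environmental_noise = 0,
                   phenotype = rexp(20))
  std <- normalize_phenotypes(ph, mode = "standard")
  expect_lt(abs(mean(std$phenotype)), 1e-12)
  expect_lt(abs(sd(std$phenotype) - 1), 1e-12)
  expect_identical(order(std$phenotype), order(ph$phenotype))
  expect_identical(std$genetic_value, ph$genetic_value)     # target = phenotype

  both <- normalize_phenotypes(ph, mode = "standard", target = "both")
  expect_lt(abs(sd(both$genetic_value) - 1), 1e-12)

  # rank-based inverse-normal values of (10, 20, 30): qnorm((r - 0.5)/3)
  q <- data.frame(individual_id = c("a", "b", "c"), trait_id = 0L,
                  genetic_value = 0, environmental_noise = 0,
                  phenotype = c(10, 20, 30))
  qn <- normalize_phenotypes(q, mode = "quantile")
  expect_close(qn$normalized_phenotype,
               c(-0.967421566101701, 0, 0.967421566101701), 1e-10)
  expect_identical(qn$phenotype, q$phenotype)               # raw preserved
  expect_identical(order(qn$normalized_phenotype), order(q$phenotype))

  const <- q; const$phenotype <- rep(1, 3)
  expect_error(normalize_phenotypes(const, mode = "standard"), "zero variance")
})

test_that("liability thresholding splits at the Gaussian quantile", {
  set.seed(701)
  ph <- data.frame(individual_id = paste0("i", 1:1000), trait_id = 0L,
                   genetic_value = 0, environmental_noise = 0,
                   phenotype = rnorm(1000, mean = 5, sd = 2))
  half <- binarize(ph, prevalence = 0.5)
  # threshold at qnorm(0.5) = 0 on the normalized scale: above-mean = case
  expect_identical(half$phenotype, as.numeric(ph$phenotype > mean(ph$phenotype)))
  expect_error(binarize(half, prevalence = 0.5), "already binary")
  expect_error(binarize(ph, prevalence = 0), "between 0 and 1")
  expect_error(binarize(ph, prevalence = 1), "between 0 and 1")
})

test_that("genetic values combine additively across graph partitions", {
  gm <- rand_gm(12, 30, seed = 801)
  whole <- build_from_matrix(gm)
  eff <- dyadic_effects(sort(sample(0:29, 10)), seed = 802)

  gv_whole <- genetic_values(whole, eff)
  expect_identical(combine_genetic_values(list(gv_whole))$individuals,
                   gv_whole$individuals)

  for (n_parts in 2:5) {
    cuts <- sort(sample(1:29, n_parts - 1))
    bounds <- c(0, cuts, 30)
    parts <- lapply(seq_len(n_parts), function(k) {
      ix <- (bounds[k] + 1):bounds[k + 1]
      sub_gm <- genotype_matrix(gm$values[, ix, drop = FALSE])
      sub_eff <- eff[eff$mutation_id %in% (ix - 1L), , drop = FALSE]
      sub_eff$mutation_id <- sub_eff$mutation_id - bounds[k]
      genetic_values(build_from_matrix(sub_gm), sub_eff)
    })
    combined <- combine_genetic_values(parts)
    expect_identical(combined$individuals$genetic_value,
                     gv_whole$individuals$genetic_value)
  }

  # a zero-effect second graph changes nothing
  zero_gv <- genetic_values(whole, data.frame(mutation_id = 0L, trait_id = 0L,
                                              effect_size = 0))
  expect_identical(
    combine_genetic_values(list(gv_whole, zero_gv))$individuals$genetic_value,
    gv_whole$individuals$genetic_value)

  # mismatched individuals are refused
  other <- genetic_values(build_from_matrix(rand_gm(5, 4, seed = 803)),
                          data.frame(mutation_id = 0L, trait_id = 0L,
                                     effect_size = 1))
  expect_error(combine_genetic_values(list(gv_whole, other)), "mismatch")
})

test_that("the end-to-end wrapper composes the stages under derived seeds", {
  gm <- rand_gm(40, 60, seed = 901)
  g <- build_from_matrix(gm)
  seed <- 902; h2 <- 0.4; m_causal <- 15

  ph <- sim_phenotypes(g, heritability = h2, num_causal = m_causal, seed = seed)

  f <- allele_frequencies(g)
  eligible <- which(f > 0 & f < 1) - 1L
  set.seed(derive_seed(seed, "causal"))
  causal <- sort(sample(eligible, m_causal))
  eff <- draw_effects_standardized(h2, causal, seed = seed)
  gv <- genetic_values_standardized(g, eff)
  noise <- environmental_noise(gv, h2 = h2, seed = seed)
  manual <- assemble_phenotypes(gv, noise)

  expect_identical(ph$phenotype, manual$phenotype)
  expect_identical(ph$genetic_value, manual$genetic_value)
  expect_identical(attr(ph, "causal_ids"), causal)

  # reruns with the same seed are identical
  ph2 <- sim_phenotypes(g, heritability = h2, num_causal = m_causal, seed = seed)
  expect_identical(as.data.frame(ph), as.data.frame(ph2))

  # deterministic path: h2 = 1, fixed effects, raw scale
  cfg <- sim_config(heritability = 1, num_causal = 5, standardized = FALSE,
                    distribution = dist_spec("fixed", value = 1), seed = 7)
  det <- sim_phenotypes(g, config = cfg)
  expect_identical(det$phenotype, det$genetic_value)
  expect_identical(det$environmental_noise, rep(0, 40))
})

test_that("multi-graph simulation equals the merged-graph run", {
  gm <- rand_gm(30, 40, seed = 911)
  whole <- build_from_matrix(gm)
  parts <- list(build_from_matrix(gm$values[, 1:17, drop = FALSE]),
                build_from_matrix(gm$values[, 18:40, drop = FALSE]))
  ph1 <- sim_phenotypes(whole, heritability = 0.6, num_causal = 12, seed = 13)
  ph2 <- sim_phenotypes(parts, heritability = 0.6, num_causal = 12, seed = 13)
  expect_identical(attr(ph1, "causal_ids"), attr(ph2, "causal_ids"))
  expect_close(ph2$genetic_value, ph1$genetic_value, 1e-12)
  expect_close(ph2$phenotype, ph1$phenotype, 1e-12)
})

test_that("binary and normalized pipelines run end to end", {
  g <- build_from_matrix(rand_gm(200, 50, seed = 921))
  bin <- sim_phenotypes(g, heritability = 0.5, num_causal = 20,
                        prevalence = 0.2, seed = 14)
  expect_true(all(bin$phenotype %in% c(0, 1)))
  expect_gt(mean(bin$phenotype), 0.05)
  expect_lt(mean(bin$phenotype), 0.4)

  qn <- sim_phenotypes(g, heritability = 0.5, num_causal = 20,
                       normalize = "quantile", seed = 15)
  expect_true("normalized_phenotype" %in% names(qn))
  expect_identical(order(qn$normalized_phenotype), order(qn$phenotype))

  expect_error(sim_config(heritability = 0.5, prevalence = 0.2,
                          standardized = FALSE), "standardized")
  expect_error(sim_phenotypes(g, heritability = 0.5, num_causal = 1e6,
                              seed = 1), "eligible")
})

test_that("multi-trait runs keep per-trait draws independent", {
  g <- build_from_matrix(rand_gm(50, 40, seed = 931))
  cfg <- sim_config(heritability = 0.5, num_causal = 10,
                    distribution = dist_spec("normal", num_traits = 2),
                    seed = 33)
  ph <- sim_phenotypes(g, config = cfg)
  expect_setequal(unique(ph$trait_id), c(0L, 1L))
  expect_identical(nrow(ph), 100L)
  wide0 <- ph$phenotype[ph$trait_id == 0]
  # adding a trait must not perturb trait 0: rerun with one trait
  cfg1 <- sim_config(heritability = 0.5, num_causal = 10,
                     distribution = dist_spec("normal", num_traits = 1),
                     seed = 33)
  ph1 <- sim_phenotypes(g, config = cfg1)
  expect_identical(ph1$phenotype, wide0)
})
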