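## Pipeline stages 2-4: additive genetic values via graph traversal (raw or
## on the standardized genotype matrix), environmental noise calibrated to a
## target narrow-sense heritability, phenotype assembly, normalization,
## liability-threshold binarization, and multi-graph (per-chromosome)
## combination. The model is y = X beta + eps with X the N-by-M diploid
## 0/1/2 matrix; individual i's genetic value is the sum of its two haploid
## sample values (samples 2i and 2i+1).

new_gv_table <- function(samples, individuals, standardized) {
  structure(list(samples = samples, individuals = individuals,
                 standardized = standardized),
            class = "genetic_value_table")
}

#' @export
print.genetic_value_table <- function(x, ...) {
  cat(sprintf("<genetic_value_table> %d individuals x %d trait(s)%s\n",
              length(unique(x$individuals$individual_id)),
              length(unique(x$individuals$trait_id)),
              if (x$standardized) " (standardized scale)" else ""))
  invisible(x)
}

scatter_beta <- function(effects, tr, M) {
  sub <- effects[effects$trait_id == tr, , drop = FALSE]
  beta <- numeric(M)
  beta[sub$mutation_id + 1L] <- sub$effect_size
  beta
}

#' Additive genetic values from a graph
#'
#' For each trait, scatters the causal effects into a length-M vector beta
#' (zero off the causal set), computes per-haploid-sample values `G beta`
#' with one downward traversal, and sums sample pairs `(2i, 2i+1)` into
#' diploid individual values `X beta`. Both the sample-level and the
#' individual-level tables are returned.
#'
#' @param grg A `grg`.
#' @param effects Effect table (`mutation_id`, `trait_id`, `effect_size`);
#'   mutation ids must exist in the graph.
#' @return A `genetic_value_table`: list with `samples`
#'   (`sample_node_id`, `trait_id`, `genetic_value`), `individuals`
#'   (`individual_id`, `trait_id`, `genetic_value`), and the scale flag
#'   `standardized`.
#' @export
genetic_values <- function(grg, effects) {
  effects <- validate_effect_table(effects, grg$mutations$mutation_id)
  traits <- sort(unique(effects$trait_id))
  if (!length(traits)) traits <- 0L
  M <- num_mutations(grg)
  samp <- list(); ind <- list()
  for (tr in traits) {
    hap <- dot_product_down(grg, scatter_beta(effects, tr, M))
    odd <- seq(1L, length(hap), by = 2L)
    samp[[length(samp) + 1L]] <- data.frame(
      sample_node_id = seq_along(hap) - 1L, trait_id = tr,
      genetic_value = hap)
    ind[[length(ind) + 1L]] <- data.frame(
      individual_id = grg$individual_ids, trait_id = tr,
      genetic_value = hap[odd] + hap[odd + 1L],
      stringsAsFactors = FALSE)
  }
  new_gv_table(do.call(rbind, samp), do.call(rbind, ind), standardized = FALSE)
}

#' Genetic values on the standardized genotype matrix
#'
#' Computes `Xs beta` where `Xs = (X - U) Sigma` is the standardized diploid
#' matrix: `U` has columns `2 f_i` (twice the alternate-allele frequency)
#' and `Sigma` is diagonal with `1 / sigma_i`, `sigma_i = sqrt(2 f_i (1 -
#' f_i))`. Implemented without materializing `Xs`: one downward traversal
#' with the scaled vector `beta_i / sigma_i` gives `X (Sigma beta)` after
#' pair-summing, and `U Sigma beta` is the constant `sum_i 2 f_i beta_i /
#' sigma_i`, subtracted from every individual. Standardized columns have
#' mean zero over individuals, so the resulting genetic values do too.
#'
#' @param grg A `grg`.
#' @param effects Effect table; every causal site must be polymorphic
#'   (`0 < f < 1`), otherwise the per-site scaling divides by zero.
#' @return A `genetic_value_table` with `standardized = TRUE`. Sample-level
#'   values are the centered halves: haploid value minus `f_i`-weighted
#'   half-offset, so that individual values remain the pair sums.
#' @export
genetic_values_standardized <- function(grg, effects) {
  effects <- validate_effect_table(effects, grg$mutations$mutation_id)
  f <- allele_frequencies(grg)
  causal <- unique(effects$mutation_id)
  bad <- causal[f[causal + 1L] %in% c(0, 1)]
  if (length(bad)) {
    stop(sprintf("causal mutation %d is monomorphic (f = %g); standardized scaling undefined",
                 bad[1], f[bad[1] + 1L]), call. = FALSE)
  }
  sigma <- standardize_sigma(f)
  traits <- sort(unique(effects$trait_id))
  if (!length(traits)) traits <- 0L
  M <- num_mutations(grg)
  samp <- list(); ind <- list()
  for (tr in traits) {
    beta <- scatter_beta(effects, tr, M)
    w <- ifelse(beta != 0, beta / sigma, 0)
    offset <- sum(2 * f * w)                 # U Sigma beta, one scalar
    hap <- dot_product_down(grg, w)
    odd <- seq(1L, length(hap), by = 2L)
    samp[[length(samp) + 1L]] <- data.frame(
      sample_node_id = seq_along(hap) - 1L, trait_id = tr,
      genetic_value = hap - offset / 2)
    ind[[length(ind) + 1L]] <- data.frame(
      individual_id = grg$individual_ids, trait_id = tr,
      genetic_value = hap[odd] + hap[odd + 1L] - offset,
      stringsAsFactors = FALSE)
  }
  new_gv_table(do.call(rbind, samp), do.call(rbind, ind), standardized = TRUE)
}

#' Combine genetic values across graphs
#'
#' Element-wise sum of genetic values from several graphs covering the same
#' individuals (additivity across chromosomes): used when genotypes are
#' split into per-chromosome graphs. All tables must list identical
#' individual id sequences and trait sets.
#'
#' @param tables List of `genetic_value_table` objects.
#' @return A single `genetic_value_table`. Sample-level tables are summed
#'   when all inputs carry them.
#' @export
combine_genetic_values <- function(tables) {
  if (inherits(tables, "genetic_value_table")) return(tables)
  stopifnot(length(tables) >= 1L)
  base <- tables[[1]]
  if (length(tables) == 1L) return(base)
  key <- function(t) paste(t$individuals$individual_id, t$individuals$trait_id)
  for (k in seq_along(tables)[-1]) {
    tk <- tables[[k]]
    if (nrow(tk$individuals) != nrow(base$individuals)) {
      stop(sprintf("graph %d: %d individual/trait rows, graph 1 has %d (mismatched samples)",
                   k, nrow(tk$individuals), nrow(base$individuals)),
           call. = FALSE)
    }
    if (!identical(key(tk), key(base))) {
      mism <- which(key(tk) != key(base))[1]
      if (is.na(mism)) mism <- min(nrow(tk$individuals), nrow(base$individuals)) + 1L
      stop(sprintf("graph %d: individual/trait sequence differs from graph 1 (first mismatch at row %d)",
                   k, mism), call. = FALSE)
    }
    base$individuals$genetic_value <-
      base$individuals$genetic_value + tk$individuals$genetic_value
    if (!is.null(base$samples) && !is.null(tk$samples) &&
        nrow(tk$samples) == nrow(base$samples)) {
      base$samples$genetic_value <-
        base$samples$genetic_value + tk$samples$genetic_value
    } else {
      base$samples <- NULL
    }
    base$standardized <- base$standardized || tk$standardized
  }
  base
}

#' Environmental noise calibrated to a heritability
#'
#' With a target narrow-sense heritability `h2`, draws per-individual noise
#' `eps ~ Normal(0, V * (1/h2 - 1))` independently per trait, where `V` is
#' the sample variance (denominator N-1) of that trait's individual genetic
#' values — so that `V / (V + Var(eps))` is `h2` in expectation. `h2 = 1`
#' gives exactly zero noise. Alternatively a [dist_spec()] draws iid noise
#' from a user-chosen distribution.
#'
#' @param gvalues A `genetic_value_table`.
#' @param h2 Heritability in `(0, 1]` (exclusive with `spec`).
#' @param spec A [dist_spec()] for user-defined noise (exclusive with `h2`).
#' @param seed Optional integer root seed; each trait uses an independent
#'   derived substream.
#' @return Data frame (`individual_id`, `trait_id`, `environmental_noise`).
#' @export
environmental_noise <- function(gvalues, h2 = NULL, spec = NULL, seed = NULL) {
  ind <- gvalues$individuals
  if (is.null(h2) == is.null(spec)) {
    stop("supply exactly one of h2 or spec", call. = FALSE)
  }
  if (!is.null(h2)) check_h2(h2)
  traits <- sort(unique(ind$trait_id))
  out <- list()
  for (tr in traits) {
    g <- ind$genetic_value[ind$trait_id == tr]
    n <- length(g)
    tr_seed <- if (is.null(seed)) NULL else derive_seed(seed, "noise", tr)
    eps <- if (!is.null(h2)) {
      if (h2 == 1) {
        rep(0, n)
      } else {
        v <- var(g)
        if (!is.finite(v) || v == 0) {
          stop("genetic values are constant; cannot scale noise to a heritability < 1",
               call. = FALSE)
        }
        with_seed(tr_seed, rnorm(n, 0, sqrt(v * (1 / h2 - 1))))
      }
    } else {
      tbl <- draw_effects(spec_single_trait(spec), seq_len(n) - 1L,
                          seed = tr_seed)
      tbl$effect_size
    }
    out[[length(out) + 1L]] <- data.frame(
      individual_id = ind$individual_id[ind$trait_id == tr],
      trait_id = tr, environmental_noise = eps, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

spec_single_trait <- function(spec) {
  spec$num_traits <- 1L
  spec$covariance <- NULL
  spec
}

#' Assemble phenotypes from genetic values and noise
#'
#' `phenotype = genetic_value + environmental_noise`, per individual per
#' trait, exactly.
#'
#' @param gvalues A `genetic_value_table`.
#' @param noise Noise table from [environmental_noise()].
#' @return Phenotype table: data frame (`individual_id`, `trait_id`,
#'   `genetic_value`, `environmental_noise`, `phenotype`).
#' @export
assemble_phenotypes <- function(gvalues, noise) {
  ind <- gvalues$individuals
  key_g <- paste(ind$individual_id, ind$trait_id)
  key_n <- paste(noise$individual_id, noise$trait_id)
  idx <- match(key_g, key_n)
  if (anyNA(idx)) stop("noise table does not cover all individuals/traits",
                       call. = FALSE)
  data.frame(individual_id = ind$individual_id, trait_id = ind$trait_id,
             genetic_value = ind$genetic_value,
             environmental_noise = noise$environmental_noise[idx],
             phenotype = ind$genetic_value + noise$environmental_noise[idx],
             stringsAsFactors = FALSE)
}

#' Normalize phenotypes (and optionally genetic values)
#'
#' Two modes, applied per trait:
#' * `"standard"`: `(x - mean) / sd` (sample sd, denominator N-1),
#'   overwriting the column in place. Errors when the sd is zero.
#' * `"quantile"`: rank-based inverse-normal transform; the value at rank
#'   `r` (1-based, average rank for ties) becomes `qnorm((r - 0.5) / N)`.
#'   Appends a `normalized_phenotype` column (and
#'   `normalized_genetic_value` with `target = "both"`), preserving the raw
#'   columns.
#'
#' Both transforms are rank-preserving.
#'
#' @param pheno Phenotype table from [assemble_phenotypes()].
#' @param mode `"standard"` or `"quantile"`.
#' @param target Normalize `"phenotype"` alone or `"both"` phenotype and
#'   genetic values.
#' @return The phenotype table, transformed as described.
#' @export
normalize_phenotypes <- function(pheno, mode = c("standard", "quantile"),
                                 target = c("phenotype", "both")) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  pheno <- as.data.frame(pheno)
  if (!nrow(pheno)) stop("empty phenotype table", call. = FALSE)
  cols <- if (target == "both") c("phenotype", "genetic_value") else "phenotype"
  for (tr in sort(unique(pheno$trait_id))) {
    rows <- pheno$trait_id == tr
    for (col in cols) {
      x <- pheno[[col]][rows]
      if (mode == "standard") {
        s <- sd(x)
        if (!is.finite(s) || s == 0) {
          stop(sprintf("cannot standard-normalize %s (trait %d): zero variance",
                       col, tr), call. = FALSE)
        }
        pheno[[col]][rows] <- (x - mean(x)) / s
      } else {
        r <- rank(x, ties.method = "average")
        new_col <- paste0("normalized_", col)
        if (is.null(pheno[[new_col]])) pheno[[new_col]] <- NA_real_
        pheno[[new_col]][rows] <- qnorm((r - 0.5) / length(x))
      }
    }
  }
  pheno
}

#' Convert continuous phenotypes to binary under a liability threshold
#'
#' Standard-normalizes each trait's phenotypes, then assigns case status 1
#' exactly when the normalized liability exceeds the Gaussian threshold
#' `qnorm(1 - prevalence)`, else control status 0, overwriting the
#' phenotype column. The theoretical quantile (not the empirical one) is
#' used, so the expected population case fraction equals the prevalence.
#' Intended to follow a standardized-mode continuous simulation; input that
#' is already binary is rejected.
#'
#' @param pheno Phenotype table.
#' @param prevalence Population prevalence K in `(0, 1)`.
#' @return The phenotype table with binary (0/1) phenotypes.
#' @export
binarize <- function(pheno, prevalence) {
  if (length(prevalence) != 1L || !is.finite(prevalence) ||
      prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  pheno <- as.data.frame(pheno)
  if (nrow(pheno) && all(pheno$phenotype %in% c(0, 1))) {
    stop("phenotypes are already binary; refusing to threshold again",
         call. = FALSE)
  }
  thr <- qnorm(1 - prevalence)
  for (tr in sort(unique(pheno$trait_id))) {
    rows <- pheno$trait_id == tr
    x <- pheno$phenotype[rows]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop("cannot binarize a constant phenotype", call. = FALSE)
    }
    pheno$phenotype[rows] <- as.numeric((x - mean(x)) / s > thr)
  }
  pheno
}

#' Simulation configuration
#'
#' Collects every knob of an end-to-end run. In standardized mode (the
#' default) effects are drawn from `Normal(0, h2 / M_causal)` unless a
#' `distribution` is given; noise is calibrated so that the realized
#' heritability is `heritability` in expectation.
#'
#' @param heritability Narrow-sense heritability h2 in `(0, 1]`; required
#'   unless `noise` is given.
#' @param num_causal Number of causal mutations (default: every polymorphic
#'   site).
#' @param standardized Simulate on the standardized genotype matrix
#'   (default `TRUE`). Required when `prevalence` is set.
#' @param distribution Optional [dist_spec()] for effect sizes (overrides
#'   the standardized default).
#' @param noise Optional [dist_spec()] for user-defined environmental noise
#'   (overrides the heritability calibration).
#' @param prevalence Optional population prevalence in `(0, 1)`; triggers
#'   binary conversion.
#' @param normalize `"none"`, `"standard"` or `"quantile"`.
#' @param normalize_target `"phenotype"` or `"both"`.
#' @param seed Optional integer root seed; each stage and trait derives an
#'   independent substream, so runs are reproducible from (seed, config)
#'   alone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(heritability = NULL, num_causal = NULL,
                       standardized = TRUE, distribution = NULL,
                       noise = NULL, prevalence = NULL,
                       normalize = c("none", "standard", "quantile"),
                       normalize_target = c("phenotype", "both"),
                       seed = NULL) {
  normalize <- match.arg(normalize)
  normalize_target <- match.arg(normalize_target)
  if (is.null(heritability) && is.null(noise)) {
    stop("supply heritability (or a user-defined noise distribution)",
         call. = FALSE)
  }
  if (!is.null(heritability)) check_h2(heritability)
  if (!is.null(prevalence)) {
    if (prevalence <= 0 || prevalence >= 1) {
      stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
    }
    if (!standardized) {
      stop("binary traits require standardized = TRUE (liability threshold on the standardized scale)",
           call. = FALSE)
    }
  }
  if (!is.null(distribution)) stopifnot(inherits(distribution, "dist_spec"))
  if (!is.null(noise)) stopifnot(inherits(noise, "dist_spec"))
  structure(list(heritability = heritability, num_causal = num_causal,
                 standardized = standardized, distribution = distribution,
                 noise = noise, prevalence = prevalence,
                 normalize = normalize, normalize_target = normalize_target,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' End-to-end phenotype simulation
#'
#' Runs the full pipeline on one graph or a list of per-chromosome graphs:
#' causal sampling, effect draws, genetic values via graph traversal
#' (standardized if configured), combination across graphs, environmental
#' noise, phenotype assembly, optional normalization and optional binary
#' conversion. With several graphs, mutation ids are treated as one
#' concatenated id space (graph order fixes the offsets), so splitting a
#' genotype matrix column-wise across graphs reproduces the single-graph
#' run exactly under the same seed.
#'
#' @param grg A `grg` or list of `grg`s over the same individuals.
#' @param config A [sim_config()]; alternatively pass its arguments via
#'   `...` (e.g. `sim_phenotypes(g, heritability = 0.3)`).
#' @param effects Optional user-supplied effect table (global mutation ids);
#'   skips causal sampling and effect drawing.
#' @param ... Arguments forwarded to [sim_config()] when `config` is NULL.
#' @return Phenotype table (`individual_id`, `trait_id`, `genetic_value`,
#'   `environmental_noise`, `phenotype`, ...), with attributes `effects`
#'   (the effect table used, global ids), `causal_ids`, `seed` (the root
#'   seed actually used) and `config`.
#' @export
sim_phenotypes <- function(grg, config = NULL, effects = NULL, ...) {
  graphs <- if (inherits(grg, "grg")) list(grg) else grg
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "grg")))
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)

  M_per <- vapply(graphs, num_mutations, integer(1))
  offsets <- c(0L, cumsum(M_per))[seq_along(graphs)]
  freqs <- lapply(graphs, allele_frequencies)
  f_all <- unlist(freqs)

  if (is.null(effects)) {
    eligible <- which(f_all > 0 & f_all < 1) - 1L
    m_causal <- if (is.null(config$num_causal)) length(eligible)
                else as.integer(config$num_causal)
    if (m_causal < 1L || m_causal > length(eligible)) {
      stop(sprintf("num_causal = %d but only %d polymorphic site(s) are eligible",
                   m_causal, length(eligible)), call. = FALSE)
    }
    causal <- with_seed(derive_seed(seed, "causal"),
                        sort(sample(eligible, m_causal)))
    effects <- if (!is.null(config$distribution)) {
      draw_effects(config$distribution, causal, seed = seed)
    } else if (config$standardized) {
      draw_effects_standardized(config$heritability, causal, seed = seed)
    } else {
      draw_effects(dist_spec("normal"), causal, seed = seed)
    }
  } else {
    effects <- validate_effect_table(effects, seq_len(sum(M_per)) - 1L)
    causal <- sort(unique(effects$mutation_id))
  }

  target_traits <- sort(unique(effects$trait_id))
  if (!length(target_traits)) target_traits <- 0L
  gvt <- combine_genetic_values(lapply(seq_along(graphs), function(g) {
    lo <- offsets[g]; hi <- offsets[g] + M_per[g]
    sub <- effects[effects$mutation_id >= lo & effects$mutation_id < hi, ,
                   drop = FALSE]
    sub$mutation_id <- sub$mutation_id - lo
    fn <- if (config$standardized) genetic_values_standardized else genetic_values
    gv <- fn(graphs[[g]], sub)
    # keep the trait set identical across graphs even when a graph holds no
    # causal site for some trait (its contribution there is exactly zero)
    ind <- gv$individuals[gv$individuals$trait_id %in% target_traits, ,
                          drop = FALSE]
    template <- gv$individuals[gv$individuals$trait_id ==
                                 gv$individuals$trait_id[1], , drop = FALSE]
    for (tr in setdiff(target_traits, unique(ind$trait_id))) {
      zero <- template
      zero$trait_id <- tr; zero$genetic_value <- 0
      ind <- rbind(ind, zero)
    }
    gv$individuals <- ind[order(ind$trait_id), , drop = FALSE]
    gv$samples <- gv$samples[gv$samples$trait_id %in% target_traits, ,
                             drop = FALSE]
    gv
  }))

  noise <- if (!is.null(config$noise)) {
    environmental_noise(gvt, spec = config$noise, seed = seed)
  } else {
    environmental_noise(gvt, h2 = config$heritability, seed = seed)
  }
  pheno <- assemble_phenotypes(gvt, noise)
  if (config$normalize != "none") {
    pheno <- normalize_phenotypes(pheno, mode = config$normalize,
                                  target = config$normalize_target)
  }
  if (!is.null(config$prevalence)) {
    pheno <- binarize(pheno, config$prevalence)
  }
  attr(pheno, "effects") <- effects
  attr(pheno, "causal_ids") <- causal
  attr(pheno, "seed") <- seed
  attr(pheno, "config") <- config
  attr(pheno, "genetic_value_table") <- gvt
  pheno
}
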