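## Pipeline stage 1: choose causal mutations and draw their effect sizes.
## Effect tables are plain data frames with columns mutation_id (0-based),
## trait_id (0-based) and effect_size; rows are unique on
## (mutation_id, trait_id). Draws depend only on the causal id set and the
## seed, never on genotype values, so two graphs with identical mutation
## ids yield identical tables.

#' Describe an effect-size distribution
#'
#' Families and their parameters:
#' * `normal`: `mean`, `sd`; with `num_traits > 1` an optional `covariance`
#'   matrix draws each mutation's effects jointly multivariate normal across
#'   traits.
#' * `exponential`: `scale` (mean); draws are positive unless
#'   `sign_flip_prob > 0`, in which case each draw's sign is flipped
#'   independently with that probability.
#' * `fixed`: `value` (deterministic).
#' * `gamma`: `shape`, `scale`; `sign_flip_prob` as for exponential.
#' * `t`: location-scale Student t with `df`, `mean`, `sd`
#'   (`mean + sd * t_df`). `df <= 2` (infinite variance) is allowed with a
#'   warning.
#'
#' Families other than multivariate normal draw each trait independently.
#'
#' @param family Distribution family name.
#' @param mean,sd,scale,value,shape,df Family-specific parameters.
#' @param num_traits Number of traits to simulate jointly (>= 1).
#' @param covariance Optional `num_traits`-square symmetric positive
#'   semi-definite matrix (normal family only).
#' @param sign_flip_prob Probability of flipping the sign of each
#'   exponential/gamma draw (default 0: draws keep their positive sign).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("normal", "exponential", "fixed", "gamma", "t"),
                      mean = 0, sd = 1, scale = 1, value = 1,
                      shape = 1, df = 5, num_traits = 1L,
                      covariance = NULL, sign_flip_prob = 0) {
  family <- match.arg(family)
  num_traits <- as.integer(num_traits)
  if (num_traits < 1L) stop("num_traits must be >= 1", call. = FALSE)
  check_pos <- function(x, nm) {
    if (any(x <= 0)) stop(sprintf("%s must be > 0", nm), call. = FALSE)
  }
  switch(family,
    normal = check_pos(sd, "sd"),
    exponential = check_pos(scale, "scale"),
    gamma = { check_pos(shape, "shape"); check_pos(scale, "scale") },
    t = {
      check_pos(df, "df"); check_pos(sd, "sd")
      if (df <= 2) warning("t-distribution with df <= 2 has infinite variance",
                           call. = FALSE)
    },
    fixed = NULL)
  if (!is.null(covariance)) {
    if (family != "normal") {
      stop("covariance is supported for the normal family only", call. = FALSE)
    }
    covariance <- as.matrix(covariance)
    if (!isTRUE(all.equal(covariance, t(covariance))) ||
        nrow(covariance) != num_traits) {
      stop("covariance must be a symmetric num_traits x num_traits matrix",
           call. = FALSE)
    }
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("covariance must be positive semi-definite", call. = FALSE)
    }
  }
  if (sign_flip_prob < 0 || sign_flip_prob > 1) {
    stop("sign_flip_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(family = family, mean = mean, sd = sd, scale = scale,
                 value = value, shape = shape, df = df,
                 num_traits = num_traits, covariance = covariance,
                 sign_flip_prob = sign_flip_prob),
            class = "dist_spec")
}

#' Sample causal mutations from a graph
#'
#' Uniform sampling without replacement among the eligible sites. Only
#' polymorphic sites (allele frequency strictly between 0 and 1) are
#' eligible: monomorphic sites carry no association signal and would make
#' standardized-mode scaling degenerate.
#'
#' @param grg A `grg`.
#' @param m_causal Number of causal mutations to draw.
#' @param seed Optional integer seed (uses the current RNG state if `NULL`).
#' @return Sorted integer vector of 0-based causal mutation ids.
#' @export
sample_causal_mutations <- function(grg, m_causal, seed = NULL) {
  f <- allele_frequencies(grg)
  eligible <- which(f > 0 & f < 1) - 1L
  m_causal <- as.integer(m_causal)
  if (m_causal < 1L || m_causal > length(eligible)) {
    stop(sprintf("m_causal = %d but only %d polymorphic site(s) are eligible",
                 m_causal, length(eligible)), call. = FALSE)
  }
  with_seed(seed, sort(sample(eligible, m_causal)))
}

#' Draw effect sizes for causal mutations
#'
#' One effect per causal mutation per trait from the given [dist_spec()].
#' Multivariate normal draws are joint across traits per mutation; all
#' other families draw each trait independently.
#'
#' @param spec A [dist_spec()].
#' @param causal_ids Integer vector of 0-based causal mutation ids.
#' @param seed Optional integer seed.
#' @return Effect table: data frame with columns `mutation_id`, `trait_id`,
#'   `effect_size`, ordered by trait then mutation.
#' @export
draw_effects <- function(spec, causal_ids, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  causal_ids <- as.integer(causal_ids)
  n <- length(causal_ids)
  traits <- seq_len(spec$num_traits) - 1L

  if (spec$family == "normal" && !is.null(spec$covariance)) {
    draws <- with_seed(seed,
      MASS::mvrnorm(n, mu = rep(spec$mean, length.out = spec$num_traits),
                    Sigma = spec$covariance))
    draws <- matrix(draws, nrow = n)  # n = 1 returns a bare vector
  } else {
    draw_one <- function(k) switch(spec$family,
      normal = rnorm(k, spec$mean, spec$sd),
      exponential = flip_signs(rexp(k, rate = 1 / spec$scale),
                               spec$sign_flip_prob),
      fixed = rep(spec$value, k),
      gamma = flip_signs(rgamma(k, shape = spec$shape, scale = spec$scale),
                         spec$sign_flip_prob),
      t = spec$mean + spec$sd * rt(k, df = spec$df))
    draws <- matrix(0, nrow = n, ncol = spec$num_traits)
    for (tr in traits) {
      tr_seed <- if (is.null(seed)) NULL else derive_seed(seed, "effects", tr)
      draws[, tr + 1L] <- with_seed(tr_seed, draw_one(n))
    }
  }
  out <- data.frame(
    mutation_id = rep(causal_ids, times = spec$num_traits),
    trait_id = rep(traits, each = n),
    effect_size = as.numeric(draws))
  validate_effect_table(out, NULL)
}

flip_signs <- function(x, prob) {
  if (prob <= 0) return(x)
  x * ifelse(runif(length(x)) < prob, -1, 1)
}

#' Draw standardized-mode effect sizes
#'
#' In standardized mode the default genetic architecture draws each causal
#' effect independently from `Normal(0, h2 / M_causal)`, so that the total
#' genetic variance on the standardized scale is `h2` in expectation.
#'
#' @param h2 Narrow-sense heritability in `(0, 1]`.
#' @param causal_ids Integer vector of 0-based causal mutation ids.
#' @param num_traits Number of traits (independent draws per trait).
#' @param seed Optional integer seed.
#' @return Effect table as in [draw_effects()].
#' @export
draw_effects_standardized <- function(h2, causal_ids, num_traits = 1L,
                                      seed = NULL) {
  check_h2(h2)
  spec <- dist_spec("normal", mean = 0, sd = sqrt(h2 / length(causal_ids)),
                    num_traits = num_traits)
  draw_effects(spec, causal_ids, seed = seed)
}

check_h2 <- function(h2) {
  if (length(h2) != 1L || !is.finite(h2) || h2 <= 0 || h2 > 1) {
    stop("heritability h2 must lie in (0, 1]", call. = FALSE)
  }
}

#' Load user-supplied effect sizes
#'
#' Accepts a data frame or a TSV file with columns `mutation_id`,
#' `effect_size` and optionally `trait_id` (default 0). Validates ids
#' against the graph, rejects duplicate (mutation, trait) pairs and
#' non-finite values; otherwise a pass-through, enabling identical-effects
#' cross-validation against any other simulator.
#'
#' @param x Data frame or TSV path.
#' @param grg Optional `grg` used to validate mutation ids.
#' @return Effect table as in [draw_effects()].
#' @export
load_custom_effects <- function(x, grg = NULL) {
  if (is.character(x)) {
    x <- read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  names(x)[names(x) == "causal_mutation_id"] <- "trait_id"
  if (!"trait_id" %in% names(x)) x$trait_id <- 0L
  need <- c("mutation_id", "effect_size")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("custom effects need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(mutation_id = as.integer(x$mutation_id),
                    trait_id = as.integer(x$trait_id),
                    effect_size = as.numeric(x$effect_size))
  valid_ids <- if (is.null(grg)) NULL else grg$mutations$mutation_id
  validate_effect_table(out, valid_ids)
}

validate_effect_table <- function(effects, valid_ids) {
  effects <- as.data.frame(effects)
  if (any(!is.finite(effects$effect_size))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  key <- paste(effects$mutation_id, effects$trait_id)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate effect for (mutation_id, trait_id) = (%s)",
                 gsub(" ", ", ", key[duplicated(key)][1])), call. = FALSE)
  }
  if (!is.null(valid_ids)) {
    unknown <- setdiff(effects$mutation_id, valid_ids)
    if (length(unknown)) {
      stop("effect refers to unknown mutation id(s): ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  effects[order(effects$trait_id, effects$mutation_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
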