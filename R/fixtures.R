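## Deterministic synthetic-data generators. Every test, example and
## benchmark in the package runs on these: no downloads, no stored binaries.

#' Generate a random phased genotype matrix
#'
#' Per mutation, a carrier count is drawn from the chosen allele-frequency
#' model and that many carrier haplotypes are assigned uniformly without
#' replacement among the 2N haploid samples. The generator is a pure
#' function of its arguments (seed included).
#'
#' Frequency models:
#' * `"uniform"`: frequency `f ~ Uniform(freq_min, freq_max)`, carrier count
#'   `round(f * 2N)`. With `freq_min == freq_max` every column has exactly
#'   `round(f * 2N)` carriers.
#' * `"sfs"`: neutral site-frequency spectrum; carrier count `k` drawn from
#'   `1 .. 2N-1` with probability proportional to `1/k`.
#'
#' @param n_individuals Number of diploid individuals N (>= 1).
#' @param n_mutations Number of mutations M.
#' @param freq_model `"uniform"` or `"sfs"`.
#' @param freq_min,freq_max Frequency bounds for the uniform model (in
#'   `(0, 1)`).
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
generate_matrix <- function(n_individuals, n_mutations,
                            freq_model = c("uniform", "sfs"),
                            freq_min = 0.05, freq_max = 0.5, seed = 1L) {
  freq_model <- match.arg(freq_model)
  if (n_individuals < 1L) stop("n_individuals must be >= 1", call. = FALSE)
  n_hap <- 2L * as.integer(n_individuals)
  set.seed(as.integer(seed))

  counts <- switch(freq_model,
    uniform = {
      if (freq_min <= 0 || freq_max >= 1 || freq_min > freq_max) {
        stop("uniform frequency bounds must satisfy 0 < freq_min <= freq_max < 1",
             call. = FALSE)
      }
      f <- runif(n_mutations, freq_min, freq_max)
      as.integer(round(f * n_hap))
    },
    sfs = {
      k <- seq_len(n_hap - 1L)
      sample(k, n_mutations, replace = TRUE, prob = 1 / k)
    })

  values <- matrix(0L, nrow = n_hap, ncol = n_mutations)
  for (i in seq_len(n_mutations)) {
    if (counts[i] > 0L) values[sample.int(n_hap, counts[i]), i] <- 1L
  }
  muts <- default_mutations(n_mutations)
  muts$position <- seq_len(n_mutations) * 100L
  genotype_matrix(values, mutations = muts)
}

#' Generate a random tree-shaped graph
#'
#' Builds a random binary tree over the 2N sample leaves by repeatedly
#' merging two uniformly chosen active lineages (a coalescent-style
#' topology), then attaches each mutation to a uniformly chosen internal
#' node. Tree graphs exercise multi-level accumulation paths that the flat
#' graphs produced by [build_from_matrix()] do not, and their edge count is
#' linear in the node count, so traversal is far cheaper than dense algebra
#' at large 2N.
#'
#' @param n_individuals Number of diploid individuals N.
#' @param n_mutations Number of mutations to scatter over internal nodes.
#' @param seed Integer seed.
#' @return A `grg`.
#' @export
generate_tree_grg <- function(n_individuals, n_mutations, seed = 1L) {
  set.seed(as.integer(seed))
  n_hap <- 2L * as.integer(n_individuals)
  children <- rep(list(integer(0)), n_hap)
  active <- seq_len(n_hap) - 1L
  while (length(active) > 1L) {
    pick <- sample.int(length(active), 2L)
    parent <- length(children)                 # 0-based id of the new node
    children[[parent + 1L]] <- active[pick]
    active <- c(active[-pick], parent)
  }
  internal <- seq(n_hap, length(children) - 1L)
  mutation_node <- internal[sample.int(length(internal), n_mutations,
                                       replace = TRUE)]
  muts <- default_mutations(n_mutations)
  muts$position <- seq_len(n_mutations) * 100L
  grg(n_hap, children, mutation_node, mutations = muts)
}

#' Golden four-sample graph used in examples and tests
#'
#' Two diploid individuals (haploid samples 0-3; individual 0 owns samples
#' 0 and 1, individual 1 owns 2 and 3) and three mutations:
#' * `m0` on node 5 (children: sample 0 and node 4), carried by samples
#'   0, 1, 2;
#' * `m1` on sample node 3, carried by sample 3 only;
#' * `m2` on node 4 (children: samples 1 and 2), carried by samples 1 and 2
#'   but not 0 or 3.
#'
#' Its dense haploid matrix (rows samples 0-3, columns m0-m2) is
#' `rbind(c(1,0,0), c(1,0,1), c(1,0,1), c(0,1,0))`.
#'
#' @return A `grg`.
#' @export
figure_grg <- function() {
  children <- list(
    integer(0), integer(0), integer(0), integer(0),  # samples 0-3
    c(1L, 2L),                                       # node 4
    c(0L, 4L))                                       # node 5
  muts <- default_mutations(3L)
  muts$position <- c(101L, 202L, 303L)
  muts$ref <- c("A", "C", "G")
  muts$alt <- c("T", "G", "A")
  grg(4L, children, mutation_node = c(5L, 3L, 4L), mutations = muts,
      individual_ids = c("ind_0", "ind_1"))
}

# dense 0/1 matrix of the golden graph, written out by hand for tests
figure_matrix <- function() {
  rbind(c(1L, 0L, 0L),
        c(1L, 0L, 1L),
        c(1L, 0L, 1L),
        c(0L, 1L, 0L))
}
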