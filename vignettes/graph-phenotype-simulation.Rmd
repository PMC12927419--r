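---
title: "Phenotype simulation on genotype representation graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype simulation on genotype representation graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grgsim)
```

## The data structure

`grgsim` encodes phased biallelic genotype hard calls as a directed acyclic
graph rather than as a matrix. The graph has one leaf ("sample node") per
haploid genome — ids `0 .. 2N-1`, with diploid individual `i` (0-based)
owning samples `2i` and `2i+1` — and internal nodes whose down edges point
toward the leaves. Mutations attach to nodes; haploid sample `j` carries
mutation `m` exactly when a directed down-path runs from `m`'s node to leaf
`j`. The implicit haploid matrix `G` (2N rows, M columns, entries 0/1) is
therefore never stored, only encoded, and shared ancestry between samples is
shared structure in the graph.

All node and mutation ids in this package are 0-based. This differs from
the 1-based convention common in statistical writing (where individual `i`
owns haploid rows `2i-1` and `2i`); 0-based indexing keeps node ids, sample
ids and mutation ids in one consistent id space across the API, the
serialized format and the CLI.

## Traversal dot products

The two workhorse operations are matrix-vector products computed by graph
traversal, one addition per edge:

* **Downward** (`dot_product_down`): each node's value is the sum of the
  input entries of its attached mutations plus the values of all its
  parents, processed parents-first; reading the leaves gives `G u`.
* **Upward** (`dot_product_up`): leaves start at `v`, internal nodes sum
  their children, processed children-first; reading each mutation's node
  gives `t(G) v`.

Traversal order is a topological sort of the DAG; ties among incomparable
nodes break by ascending node id so every traversal, and hence every output
file, is deterministic. Duplicate parallel edges are structurally forbidden
(the accumulation rule would count a child's contribution twice), and
validation rejects them at construction time.

Allele frequencies come from a single upward pass with the all-ones vector:
`f = t(G) 1 / 2N`, exact integer counts divided by `2N`.

## Building a graph from a matrix, losslessly

The builder (`build_from_matrix`) is intentionally simple and prioritizes
the lossless contract over compression ratio:

1. **Stage 1 (always):** one internal node per *distinct carrier set*, with
   direct edges to its carrier samples. Mutations whose carrier sets are
   identical share a node. This flat encoding is already lossless.
2. **Stage 2 (`compress = TRUE`):** a greedy pass repeatedly extracts the
   child pair shared by the most parents (ties by ascending child ids) into
   a new internal node and rewires those parents. Each extraction with `k`
   parents reduces the sum of `(degree - 1)` over internal nodes by
   `k - 1 >= 1`, so the pass terminates; the edge count never increases,
   and reachability — hence the decoded matrix — never changes.

`decode_to_matrix` inverts the encoding by direct per-mutation reachability
search. That route shares no code with the accumulation traversals, so the
pair `build -> decode` and the pair `traversal vs dense algebra` provide two
independent cross-checks, both exercised heavily in the test suite. The
greedy pass enumerates child pairs within each parent and is intended for
the moderately sized graphs used in tests and examples; the flat stage-1
encoding is the default for large inputs.

A mutation attached to a node that reaches no samples is legal (frequency
0); such sites are simply never eligible for causal sampling.

## The simulation pipeline

Phenotypes follow the standard additive model `y = X beta + eps`, with `X`
the N-by-M diploid 0/1/2 matrix obtained by summing haplotype pairs.

**Stage 1 — causal effects.** `num_causal` mutations are sampled uniformly
without replacement among polymorphic sites (`0 < f < 1`; monomorphic sites
carry no signal and break standardized scaling). Effect sizes come from
built-in families — normal, exponential, fixed, gamma, location-scale
Student t — univariate or, for the normal family, jointly multivariate
across traits with a user covariance. The other families have no canonical
multivariate construction, so they draw each trait independently.
Exponential and gamma draws are kept positive by default; a
`sign_flip_prob` knob randomizes signs when a symmetric architecture is
wanted. User-supplied effect tables bypass stage 1 entirely, which is also
how one feeds *identical* effects into this simulator and any other
implementation for cross-validation.

**Stage 2 — genetic values.** One downward traversal per trait computes
`G beta`; haplotype pairs are summed into individual values `X beta`. In
**standardized mode** the genetic value is computed on
`Xs = (X - U) Sigma`, where column `i` of `U` is `2 f_i` and `Sigma` is
diagonal with `1 / sigma_i`. We take `sigma_i = sqrt(2 f_i (1 - f_i))`, the
standard deviation of a 0/1/2 genotype under Hardy–Weinberg proportions —
the natural reading of "inverse standard deviation" scaling. Rather than
materializing `Xs`, the package computes `X (Sigma beta) - U Sigma beta`:
the first term is a traversal with the scaled vector `beta_i / sigma_i`,
the second is one scalar `sum(2 f_i beta_i / sigma_i)` subtracted from
every individual. Standardized columns are mean-centered, so standardized
genetic values average to zero over individuals (the suite asserts this to
1e-9).

In standardized mode the default architecture draws
`beta ~ Normal(0, h2 / M_causal)`, giving total genetic variance `h2` on
the standardized scale in expectation.

**Stage 3 — environmental noise.** With a target heritability,
`eps ~ Normal(0, V (1/h2 - 1))` iid per individual, where `V` is the sample
variance (denominator `N - 1`; the conventional unbiased estimator) of the
current trait's individual genetic values — standardized values when
standardized mode is on. `h2 = 1` yields exactly zero noise. A user
`dist_spec` may replace the calibrated Gaussian entirely. Noise is drawn
independently per trait; cross-trait environmental correlation is out of
scope.

**Stage 4 — assembly and transforms.** `phenotype = genetic_value + eps`,
exactly. Optional normalization is `standard` (`(x - mean)/sd`, overwriting
in place) or `quantile` (rank-based inverse normal,
`qnorm((r - 0.5)/N)` with average ranks for ties, appended as
`normalized_phenotype` so the raw column survives). Normalization is
applied *after* the noise variance has been computed from the unnormalized
values, so the heritability calibration always refers to the
pre-normalization scale. Binary traits threshold the standard-normalized
phenotype at the theoretical Gaussian quantile `qnorm(1 - K)` — the
theoretical rather than empirical quantile, because the model targets the
*population* prevalence `K`, not an exact sample case count — and overwrite
the phenotype column with 0/1 status. Binary simulation requires
standardized mode, where the liability scale is well defined.

## Multiple graphs (per-chromosome input)

`sim_phenotypes` accepts a list of graphs over the same individuals in the
same order. Mutation ids are treated as one concatenated id space in list
order; causal sampling and effect draws happen once, globally, and each
graph contributes the genetic value of its own mutation block
(standardized frequencies and the centering scalar are computed per graph
and summed). Consequence: column-splitting one genotype matrix across
graphs reproduces the single-graph run — the same causal set, the same
effects, and genetic values equal up to floating-point summation order.
The combination itself (`combine_genetic_values`) is an element-wise sum
and is exact; when effect sizes are exactly representable (the dyadic
grids used in the tests), split and merged runs are bit-identical.

## Random-number policy

One root seed drives everything. Each stage derives an independent
substream seed keyed by `(root seed, stage name, trait index)`
(`derive_seed`), so adding a trait or invoking an optional stage never
perturbs draws made elsewhere: trait 0 of a two-trait run equals the
one-trait run under the same root seed, and reruns are bit-identical. The
CLI logs the resolved configuration — including a generated seed when the
user gave none — to a `.run.json` sidecar so any run can be replayed.

## What the synthetic generators emulate — and what they do not

`generate_matrix` draws each mutation's carrier count from a frequency
model (uniform bounds, or a neutral `1/k` site-frequency spectrum) and
scatters carriers uniformly among haplotypes. Columns are therefore
independent: there is no linkage disequilibrium, no shared genealogy, no
population structure, and no recombination map. `generate_tree_grg` builds
a random binary coalescent-style topology, which exercises deep multi-level
accumulation paths and realizes the regime where graph traversal is far
cheaper than dense algebra (edges grow linearly in samples rather than as
`2N x M`). Passing tests on these fixtures validates the *algebra* —
traversals, losslessness, calibration — not robustness to the
LD structure, relatedness or missingness of real cohort data. Real phased
VCFs are read with hard-call semantics only; missing or unphased genotypes
are rejected rather than imputed, since the graph encodes hard calls and
any imputation policy would be silent data invention.

## Numerical choices and study sizes

* Traversal products agree with dense algebra to a relative 1e-10 in the
  suite; the operations themselves are exact sums, so discrepancies are
  pure floating-point association.
* Calibration checks run at N = 2,000 individuals, M = 5,000 mutations,
  500 causal (heritability; 50 replicates per target value) and N = 10,000
  with 100 replicates (prevalence at K = 0.01, 0.1, 0.5); both recover
  their targets within Monte-Carlo error (3 standard errors of the
  replicate mean). These sizes give standard errors around 1e-3 on the
  heritability ratio while keeping a full suite run in minutes.
* The scaling comparison times traversal against BLAS `X %*% beta` on
  identical pre-decoded tree fixtures at 1e3–1e5 haploid samples, with the
  variant count growing in proportion to the sample count (10–1,000) as it
  does in sequencing cohorts, and with the decode cost excluded from both
  sides. Tree edges grow linearly in samples while the dense product grows
  as samples × variants, which is exactly the asymmetry the graph encoding
  exploits.
* Degenerate inputs fail loudly: zero-variance phenotypes cannot be
  standard-normalized or binarized, constant genetic values cannot be
  scaled to `h2 < 1`, monomorphic causal sites name the offending mutation,
  and already-binary phenotypes are refused by `binarize`.

## Worked example

```{r example}
gm <- generate_matrix(n_individuals = 200, n_mutations = 500, seed = 42)
g  <- build_from_matrix(gm)
g

ph <- sim_phenotypes(g, heritability = 0.3, num_causal = 50, seed = 42)
head(ph, 3)
var(ph$genetic_value) / var(ph$phenotype)
```

The realized heritability of a single replicate fluctuates around the 0.3
target; averaging `var(genetic)/var(phenotype)` over independent seeds
recovers it to Monte-Carlo precision (see `scripts/acceptance.R` in the
source repository).

## Known limitations

* The greedy compressor is quadratic in node degree and meant for modest
  graphs; it is a best-effort size reduction, not a reproduction of any
  particular construction algorithm's compression ratio.
* No dominance, epistasis, gene-environment interaction, frequency-dependent
  (alpha-model) architectures, LD-aware causal sampling, or ascertained
  case-control sampling.
* Binary phenotypes require standardized mode; raw-scale liabilities are
  not supported.
* VCF input must be phased, diploid and complete; BGEN/PLINK BED are not
  read.
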