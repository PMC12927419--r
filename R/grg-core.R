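#' @useDynLib grgsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm rnorm rexp rgamma rt runif sd var
#' @importFrom utils head read.table write.table
NULL

## Node-id convention (0-based, documented throughout):
##   - a graph over N diploid individuals has 2N haploid sample leaves with
##     ids 0 .. 2N-1; individual i (0-based) owns samples 2i and 2i+1;
##   - internal nodes take ids >= 2N;
##   - down edges run from ancestral nodes toward the sample leaves.
## Sample j carries mutation m iff a directed down-path exists from the node
## m is attached to down to leaf j. This is the lossless encoding of the
## phased 0/1 haploid genotype matrix G (2N rows, M columns).

#' Construct a genotype representation graph
#'
#' Builds the package's core data structure: an immutable directed acyclic
#' graph over `n_haploid` sample leaves (node ids `0 .. n_haploid-1`), with
#' mutations attached to nodes. A sample carries a mutation exactly when a
#' directed down-path connects the mutation's node to that leaf, so the graph
#' losslessly encodes a phased 0/1 genotype matrix without storing it.
#'
#' Node ids are 0-based; diploid individual `i` (0-based) owns haploid
#' samples `2*i` and `2*i + 1`.
#'
#' @param n_haploid Number of haploid samples (2N; must be even, >= 2).
#' @param children List with one element per node (element `k` describes node
#'   `k - 1`): an integer vector of 0-based child node ids (down edges).
#'   Sample nodes must have no children. May be shorter than the total node
#'   count only if all trailing nodes are childless.
#' @param mutation_node Integer vector, one entry per mutation: the 0-based
#'   id of the node each mutation is attached to. Mutation ids are the dense
#'   indices `0 .. M-1` given by position in this vector.
#' @param mutations Optional data frame of mutation metadata with columns
#'   `mutation_id`, `position`, `ref`, `alt`, `frequency`; defaults are
#'   synthesized when omitted.
#' @param individual_ids Optional character vector of N diploid individual
#'   identifiers; defaults to `ind_0 .. ind_{N-1}`.
#' @param validate Check all structural invariants (acyclicity, childless
#'   leaves, no duplicate edges, id ranges). Leave `TRUE` unless the caller
#'   guarantees them.
#' @return An object of class `grg`.
#' @export
grg <- function(n_haploid, children, mutation_node, mutations = NULL,
                individual_ids = NULL, validate = TRUE) {
  n_haploid <- as.integer(n_haploid)
  if (length(n_haploid) != 1L || is.na(n_haploid) || n_haploid < 2L ||
      n_haploid %% 2L != 0L) {
    stop("n_haploid must be a single even integer >= 2", call. = FALSE)
  }
  children <- lapply(children, function(x) as.integer(x))
  all_child <- unlist(children, use.names = FALSE)
  n_nodes <- max(length(children), n_haploid,
                 if (length(all_child)) max(all_child) + 1L else 0L,
                 if (length(mutation_node)) max(as.integer(mutation_node)) + 1L else 0L)
  if (length(children) < n_nodes) {
    children <- c(children, rep(list(integer(0)), n_nodes - length(children)))
  }
  mutation_node <- as.integer(mutation_node)
  M <- length(mutation_node)

  if (is.null(mutations)) mutations <- default_mutations(M)
  mutations <- validate_mutations(mutations, M)
  N <- n_haploid %/% 2L
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind_", seq_len(N) - 1L)
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != N) {
    stop(sprintf("individual_ids has length %d; expected N = %d",
                 length(individual_ids), N), call. = FALSE)
  }

  deg <- lengths(children)
  edge_ptr <- c(0L, cumsum(deg))
  edge_child <- if (sum(deg)) unlist(children, use.names = FALSE) else integer(0)

  g <- structure(
    list(n_haploid = n_haploid, n_nodes = n_nodes,
         edge_ptr = edge_ptr, edge_child = edge_child,
         mutation_node = mutation_node, mutations = mutations,
         individual_ids = individual_ids, topo_down = NULL),
    class = "grg")

  if (validate) validate_grg(g)
  topo <- cpp_topo(g$n_nodes, g$edge_ptr, g$edge_child, FALSE)
  if (!topo$ok) stop_cycle(topo$cycle_edge)
  g$topo_down <- topo$order
  g
}

default_mutations <- function(M) {
  data.frame(mutation_id = seq_len(M) - 1L,
             position = seq_len(M),
             ref = rep("A", M),
             alt = rep("T", M),
             frequency = rep(NA_real_, M),
             stringsAsFactors = FALSE)
}

validate_mutations <- function(mutations, M) {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  need <- c("mutation_id", "position", "ref", "alt")
  miss <- setdiff(need, names(mutations))
  if (length(miss)) {
    stop("mutations table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"frequency" %in% names(mutations)) mutations$frequency <- NA_real_
  if (nrow(mutations) != M) {
    stop(sprintf("mutations table has %d rows; expected M = %d",
                 nrow(mutations), M), call. = FALSE)
  }
  if (M && !identical(as.integer(mutations$mutation_id), seq_len(M) - 1L)) {
    stop("mutation_id must be the dense sequence 0..M-1", call. = FALSE)
  }
  mutations$mutation_id <- as.integer(mutations$mutation_id)
  mutations$position <- as.numeric(mutations$position)
  mutations$ref <- as.character(mutations$ref)
  mutations$alt <- as.character(mutations$alt)
  mutations$frequency <- as.numeric(mutations$frequency)
  f <- mutations$frequency
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("mutation frequencies must lie in [0, 1]", call. = FALSE)
  }
  rownames(mutations) <- NULL
  mutations
}

stop_cycle <- function(edge) {
  stop(sprintf("graph contains a cycle (includes down edge %d -> %d)",
               edge[1], edge[2]), call. = FALSE)
}

validate_grg <- function(g) {
  if (length(g$edge_child) &&
      (min(g$edge_child) < 0L || max(g$edge_child) >= g$n_nodes)) {
    stop("child id out of range", call. = FALSE)
  }
  if (any(g$mutation_node < 0L | g$mutation_node >= g$n_nodes)) {
    stop("mutation attached to a nonexistent node", call. = FALSE)
  }
  deg <- diff(g$edge_ptr)
  if (any(deg[seq_len(g$n_haploid)] > 0L)) {
    bad <- which(deg[seq_len(g$n_haploid)] > 0L)[1] - 1L
    stop(sprintf("sample node %d has children; sample leaves must be childless",
                 bad), call. = FALSE)
  }
  for (n in which(deg > 1L)) {
    ch <- g$edge_child[(g$edge_ptr[n] + 1L):g$edge_ptr[n + 1L]]
    if (anyDuplicated(ch)) {
      stop(sprintf("node %d lists a child twice (parallel edges would double-count)",
                   n - 1L), call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.grg <- function(x, ...) {
  cat(sprintf("<grg> %d haploid samples (%d individuals), %d mutations, %d nodes, %d edges\n",
              x$n_haploid, x$n_haploid %/% 2L, num_mutations(x),
              x$n_nodes, num_edges(x)))
  invisible(x)
}

#' Graph size accessors
#'
#' @param grg A `grg` object.
#' @return `num_samples()`: haploid sample count 2N; `num_individuals()`: N;
#'   `num_mutations()`: M; `num_nodes()`: total node count; `num_edges()`:
#'   down-edge count.
#' @export
num_samples <- function(grg) grg$n_haploid

#' @rdname num_samples
#' @export
num_individuals <- function(grg) grg$n_haploid %/% 2L

#' @rdname num_samples
#' @export
num_mutations <- function(grg) length(grg$mutation_node)

#' @rdname num_samples
#' @export
num_nodes <- function(grg) grg$n_nodes

#' @rdname num_samples
#' @export
num_edges <- function(grg) length(grg$edge_child)

#' Children adjacency of a graph
#'
#' @param grg A `grg` object.
#' @return List with one integer vector of 0-based child ids per node
#'   (element `k` is node `k - 1`).
#' @export
grg_children <- function(grg) {
  deg <- diff(grg$edge_ptr)
  split_ids <- rep.int(seq_along(deg), deg)
  out <- rep(list(integer(0)), grg$n_nodes)
  if (length(grg$edge_child)) {
    filled <- split(grg$edge_child, split_ids)
    out[as.integer(names(filled))] <- filled
  }
  out
}

#' Topological order of the graph
#'
#' Orders all nodes so that dependencies of the chosen traversal direction
#' come first: `"down"` places every parent before all of its children (the
#' order used to push mutation effects toward the sample leaves), `"up"`
#' places every child before all of its parents (the order used to pull
#' carrier counts toward the roots). Ties among incomparable nodes break by
#' ascending node id, so the order is deterministic.
#'
#' @param grg A `grg` object.
#' @param direction `"down"` or `"up"`.
#' @return Integer vector of 0-based node ids, each node exactly once.
#' @export
topological_order <- function(grg, direction = c("down", "up")) {
  direction <- match.arg(direction)
  res <- cpp_topo(grg$n_nodes, grg$edge_ptr, grg$edge_child,
                  direction == "up")
  if (!res$ok) stop_cycle(res$cycle_edge)
  res$order
}

#' Graph-traversal dot products
#'
#' The two matrix-vector products of the implicit haploid genotype matrix
#' `G` (2N-by-M, entries 0/1), computed by graph traversal without ever
#' materializing `G`:
#'
#' * `dot_product_down(grg, u)` returns `G %*% u` (length 2N): each node
#'   accumulates the effects of its attached mutations plus the accumulated
#'   values of all its parents, processed parents-first; the values at the
#'   sample leaves are the per-haploid-genome results.
#' * `dot_product_up(grg, v)` returns `t(G) %*% v` (length M): sample leaves
#'   start at `v`, internal nodes sum their children, processed
#'   children-first; each mutation reads the value at its node.
#'
#' Both traversals cost one addition per edge.
#'
#' @param grg A `grg` object.
#' @param u Numeric vector of length M (one entry per mutation).
#' @param v Numeric vector of length 2N (one entry per haploid sample).
#' @return Numeric vector: length 2N for `dot_product_down` (sample-node id
#'   order), length M for `dot_product_up` (mutation id order).
#' @export
dot_product_down <- function(grg, u) {
  u <- as.numeric(u)
  if (length(u) != num_mutations(grg)) {
    stop(sprintf("u has length %d; expected M = %d mutations",
                 length(u), num_mutations(grg)), call. = FALSE)
  }
  cpp_dot_down(grg$n_nodes, grg$n_haploid, grg$edge_ptr, grg$edge_child,
               grg$topo_down, grg$mutation_node, u)
}

#' @rdname dot_product_down
#' @export
dot_product_up <- function(grg, v) {
  v <- as.numeric(v)
  if (length(v) != num_samples(grg)) {
    stop(sprintf("v has length %d; expected 2N = %d haploid samples",
                 length(v), num_samples(grg)), call. = FALSE)
  }
  cpp_dot_up(grg$n_nodes, grg$n_haploid, grg$edge_ptr, grg$edge_child,
             grg$topo_down, grg$mutation_node, v)
}

#' Alternate-allele frequencies from the graph
#'
#' Carrier count of every mutation over the 2N haploid samples divided by
#' 2N, obtained from a single upward traversal with the all-ones vector.
#' This equals the column means of the implicit haploid genotype matrix
#' exactly (integer counts over 2N).
#'
#' @param grg A `grg` object.
#' @return Numeric vector of length M with values in `[0, 1]`.
#' @seealso [grg_set_frequencies()] to store the result in the graph's
#'   mutation table; [standardize_sigma()] for the per-site standard
#'   deviation `sqrt(2 f (1 - f))` used by the standardized genotype matrix.
#' @export
allele_frequencies <- function(grg) {
  dot_product_up(grg, rep(1, num_samples(grg))) / num_samples(grg)
}

#' @rdname allele_frequencies
#' @return `grg_set_frequencies()` returns the graph with
#'   `mutations$frequency` populated.
#' @export
grg_set_frequencies <- function(grg) {
  grg$mutations$frequency <- allele_frequencies(grg)
  grg
}

#' Per-site standard deviation of the diploid genotype
#'
#' `sqrt(2 * f * (1 - f))`: the standard deviation of a 0/1/2 diploid
#' genotype at alternate-allele frequency `f` under Hardy-Weinberg
#' proportions. Zero exactly when the site is monomorphic (`f` of 0 or 1).
#'
#' @param f Numeric vector of allele frequencies in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @export
standardize_sigma <- function(f) sqrt(2 * f * (1 - f))

#' Dense genotype matrix container
#'
#' A phased haploid genotype matrix: 2N rows (haploid samples, rows `2i+1`
#' and `2i+2` of the matrix belong to 0-based individual `i`), M columns
#' (mutations), entries 0/1.
#'
#' @param values Integer/numeric matrix of 0s and 1s with an even row count.
#' @param mutations Optional mutation metadata (as in [grg()]).
#' @param individual_ids Optional character vector of N individual ids.
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `mutations`, `individual_ids`.
#' @export
genotype_matrix <- function(values, mutations = NULL, individual_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) %% 2L != 0L) {
    stop("genotype matrix must have an even number of rows (two haplotypes per individual)",
         call. = FALSE)
  }
  if (length(values) && !all(values == 0L | values == 1L)) {
    stop("genotype matrix entries must be 0 or 1 (phased hard calls)",
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  M <- ncol(values)
  if (is.null(mutations)) mutations <- default_mutations(M)
  mutations <- validate_mutations(mutations, M)
  N <- nrow(values) %/% 2L
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(N) - 1L)
  if (length(individual_ids) != N) {
    stop("individual_ids length must equal the number of diploid individuals",
         call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(list(values = values, mutations = mutations,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d haploid samples x %d mutations\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Diploid genotype matrix from a phased haploid one
#'
#' Sums haplotype rows `2i+1` and `2i+2` into individual `i`'s 0/1/2 row.
#'
#' @param gm A `genotype_matrix` (or plain 0/1 matrix with even row count).
#' @return N-by-M integer matrix of 0/1/2 counts.
#' @export
diploid_matrix <- function(gm) {
  values <- if (inherits(gm, "genotype_matrix")) gm$values else as.matrix(gm)
  odd <- seq(1L, nrow(values), by = 2L)
  values[odd, , drop = FALSE] + values[odd + 1L, , drop = FALSE]
}

#' Build a graph from a dense genotype matrix (lossless)
#'
#' Stage 1 creates one internal node per distinct carrier set (mutations
#' sharing an identical carrier set share a node) with direct down edges to
#' its carrier samples; this flat encoding is already lossless. With
#' `compress = TRUE`, a greedy second stage repeatedly extracts the child
#' pair shared by the most parents (ties broken by ascending child ids)
#' into a new internal node until no pair is shared by two or more parents.
#' Compression changes only the internal wiring, never which samples each
#' mutation reaches, and never increases the edge count.
#'
#' `decode_to_matrix(build_from_matrix(gm))` reproduces `gm` exactly, with
#' or without compression.
#'
#' @param gm A `genotype_matrix` (or plain 0/1 matrix with even row count).
#' @param compress Run the greedy shared-subset factoring stage.
#' @return A `grg` carrying `gm`'s mutations and individual ids.
#' @export
build_from_matrix <- function(gm, compress = FALSE) {
  if (!inherits(gm, "genotype_matrix")) gm <- genotype_matrix(gm)
  values <- gm$values
  n_haploid <- nrow(values)
  M <- ncol(values)

  carriers <- lapply(seq_len(M), function(i) which(values[, i] == 1L) - 1L)
  keys <- vapply(carriers, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  node_of_key <- match(keys, keys[first])          # 1-based distinct-set index
  distinct <- carriers[first]

  children <- c(rep(list(integer(0)), n_haploid), distinct)
  mutation_node <- n_haploid + node_of_key - 1L

  if (compress && length(distinct)) {
    children <- compress_children(children, n_haploid)
  }
  grg(n_haploid, children, mutation_node, mutations = gm$mutations,
      individual_ids = gm$individual_ids, validate = FALSE)
}

# Greedy shared-pair factoring. Repeatedly finds the (a, b) child pair
# present in >= 2 parents, extracts it into a fresh node and rewires those
# parents. Terminates: each extraction with k parents lowers
# sum(pmax(lengths - 1, 0)) by k - 1 >= 1.
compress_children <- function(children, n_haploid) {
  repeat {
    keys <- character(0)
    for (ch in children) {
      if (length(ch) >= 2L) {
        ch <- sort(ch)
        cmb <- utils::combn(ch, 2L)
        keys <- c(keys, paste(cmb[1L, ], cmb[2L, ], sep = "_"))
      }
    }
    if (!length(keys)) break
    tab <- table(keys)
    tab <- tab[tab >= 2L]
    if (!length(tab)) break
    top <- tab[tab == max(tab)]
    pairs <- do.call(rbind, strsplit(names(top), "_", fixed = TRUE))
    storage.mode(pairs) <- "integer"
    pick <- order(pairs[, 1L], pairs[, 2L])[1L]
    a <- pairs[pick, 1L]; b <- pairs[pick, 2L]
    z <- length(children)                          # new node's 0-based id
    children[[z + 1L]] <- c(a, b)
    for (k in seq_len(z)) {
      ch <- children[[k]]
      if (length(ch) >= 2L && a %in% ch && b %in% ch) {
        children[[k]] <- c(ch[!(ch %in% c(a, b))], z)
      }
    }
  }
  children
}

#' Decode a graph back to its dense genotype matrix
#'
#' Column `i` is the indicator of the samples reachable from mutation `i`'s
#' node by down edges, found by direct per-mutation reachability search.
#' This route is algorithmically independent of the accumulation traversals
#' in [dot_product_down()], so the two can cross-validate each other.
#'
#' @param grg A `grg` object.
#' @return A `genotype_matrix` (2N-by-M, entries 0/1).
#' @export
decode_to_matrix <- function(grg) {
  values <- cpp_decode(grg$n_nodes, grg$n_haploid, grg$edge_ptr,
                       grg$edge_child, grg$mutation_node)
  genotype_matrix(values, mutations = grg$mutations,
                  individual_ids = grg$individual_ids)
}
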