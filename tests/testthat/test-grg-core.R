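test_that("topological order respects every edge in both directions", {
  # leaves only: any permutation is valid, every node appears once
  g0 <- grg(4, rep(list(integer(0)), 4), mutation_node = integer(0))
  expect_setequal(topological_order(g0, "down"), 0:3)

  g <- figure_grg()
  down <- topological_order(g, "down")
  expect_true(match(4, down) < match(1, down))
  expect_true(match(4, down) < match(2, down))
  up <- topological_order(g, "up")
  expect_true(match(1, up) < match(4, up))
  expect_true(match(2, up) < match(4, up))

  # random DAGs: brute-force pairwise check against the edge list
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20L
    children <- rep(list(integer(0)), n)
    # edges only from higher ids to lower ids over the first 8 "leaves"
    for (p in 9:20) {
      k <- sample(0:3, 1)
      if (k > 0) children[[p]] <- sample(0:(p - 2), k)
    }
    children[1:8] <- rep(list(integer(0)), 8)
    g <- grg(8, children, mutation_node = integer(0))
    down <- topological_order(g, "down")
    up <- topological_order(g, "up")
    pos_d <- match(0:(n - 1), down)
    pos_u <- match(0:(n - 1), up)
    for (p in seq_len(n)) {
      for (c in children[[p]]) {
        expect_lt(pos_d[p], pos_d[c + 1])
        expect_gt(pos_u[p], pos_u[c + 1])
      }
    }
    expect_setequal(down, 0:(n - 1))
    expect_setequal(up, 0:(n - 1))
  }
})

test_that("a cyclic edge set is rejected with the offending edge named", {
  children <- list(integer(0), integer(0),  # samples 0, 1
                   c(3L),                   # node 2 -> 3
                   c(2L))                   # node 3 -> 2 (cycle)
  expect_error(grg(2, children, mutation_node = integer(0)), "cycle")
})

test_that("structural invariants are enforced", {
  expect_error(grg(3, rep(list(integer(0)), 3), integer(0)), "even")
  expect_error(  # sample with children
    grg(2, list(c(1L), integer(0)), integer(0)), "childless")
  expect_error(  # duplicate child
    grg(2, list(integer(0), integer(0), c(0L, 0L)), integer(0)), "twice")
  expect_error(  # invalid mutation attachment
    grg(2, list(integer(0), integer(0)), mutation_node = -1L), "nonexistent")
})

test_that("downward traversal equals G u on the golden graph", {
  g <- figure_grg()
  expect_identical(dot_product_down(g, c(0, 0, 0)), rep(0, 4))
  # m2 sits on node 4 with children samples 1 and 2
  expect_identical(dot_product_down(g, c(0, 0, 1)), c(0, 1, 1, 0))
  expect_error(dot_product_down(g, c(1, 2)), "expected M")
})

test_that("upward traversal equals t(G) v on the golden graph", {
  g <- figure_grg()
  expect_identical(dot_product_up(g, rep(0, 4)), rep(0, 3))
  counts <- dot_product_up(g, rep(1, 4))
  expect_identical(counts[3], 2)      # m2 carried by two samples
  expect_identical(counts, c(3, 1, 2))
  expect_error(dot_product_up(g, 1:3), "expected 2N")
})

test_that("traversal products match the dense oracle on random fixtures", {
  for (seed in 1:10) {
    gm <- rand_gm(4, 6, seed)
    g <- build_from_matrix(gm, compress = seed %% 2 == 0)
    set.seed(seed + 100)
    u <- rnorm(6); v <- rnorm(8)
    expect_close(dot_product_down(g, u), dense_down(gm, u), 1e-10)
    expect_close(dot_product_up(g, v), dense_up(gm, v), 1e-10)
  }
  # deeper accumulation paths via tree-shaped graphs
  for (seed in 1:5) {
    tg <- generate_tree_grg(6, 9, seed = seed)
    gm <- decode_to_matrix(tg)
    set.seed(seed + 200)
    u <- rnorm(9); v <- rnorm(12)
    expect_close(dot_product_down(tg, u), dense_down(gm, u), 1e-10)
    expect_close(dot_product_up(tg, v), dense_up(gm, v), 1e-10)
  }
})

test_that("traversals are linear and mutually adjoint", {
  tg <- generate_tree_grg(8, 12, seed = 21)
  set.seed(22)
  u1 <- rnorm(12); u2 <- rnorm(12); v <- rnorm(16)
  lhs <- dot_product_down(tg, 2.5 * u1 - 0.7 * u2)
  rhs <- 2.5 * dot_product_down(tg, u1) - 0.7 * dot_product_down(tg, u2)
  expect_close(lhs, rhs, 1e-10)
  # <v, G u> == <G^T v, u>
  expect_close(sum(v * dot_product_down(tg, u1)),
               sum(dot_product_up(tg, v) * u1), 1e-10)
})

test_that("allele frequencies are exact carrier fractions", {
  g <- figure_grg()
  expect_identical(allele_frequencies(g), c(0.75, 0.25, 0.5))

  # a mutation reaching no samples has frequency zero
  g0 <- grg(4, c(rep(list(integer(0)), 4), list(integer(0))),
            mutation_node = 4L)
  expect_identical(allele_frequencies(g0), 0)

  gm <- rand_gm(10, 25, seed = 31)
  g <- build_from_matrix(gm)
  expect_identical(allele_frequencies(g), colMeans(gm$values))
  g <- grg_set_frequencies(g)
  expect_identical(g$mutations$frequency, colMeans(gm$values))
})

test_that("build and decode are mutually inverse (losslessness)", {
  # all-zero matrix: mutation nodes reach no samples
  zero <- genotype_matrix(matrix(0L, 4, 3))
  gz <- build_from_matrix(zero)
  expect_identical(decode_to_matrix(gz)$values, zero$values)
  expect_identical(allele_frequencies(gz), rep(0, 3))

  # identical carrier sets share one node
  dup <- genotype_matrix(cbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L)))
  gd <- build_from_matrix(dup, compress = TRUE)
  expect_identical(gd$mutation_node[1], gd$mutation_node[2])

  for (seed in 1:30) {
    set.seed(seed)
    n_ind <- sample(2:12, 1); n_mut <- sample(1:20, 1)
    gm <- rand_gm(n_ind, n_mut, seed = seed + 500)
    flat <- build_from_matrix(gm, compress = FALSE)
    comp <- build_from_matrix(gm, compress = TRUE)
    expect_identical(decode_to_matrix(flat)$values, gm$values)
    expect_identical(decode_to_matrix(comp)$values, gm$values)
    expect_lte(num_edges(comp), num_edges(flat))
  }

  gm <- rand_gm(25, 40, seed = 77)
  flat <- build_from_matrix(gm)
  comp <- build_from_matrix(gm, compress = TRUE)
  expect_identical(decode_to_matrix(comp)$values, gm$values)
  expect_lte(num_edges(comp), num_edges(flat))

  expect_error(build_from_matrix(matrix(2L, 4, 1)), "0 or 1")
  expect_error(build_from_matrix(matrix(0L, 3, 1)), "even")
})

test_that("decode of the golden graph matches its stated carrier sets", {
  expect_identical(decode_to_matrix(figure_grg())$values, figure_matrix())
  # empty mutation set decodes to a 2N x 0 matrix
  g0 <- grg(4, rep(list(integer(0)), 4), integer(0))
  expect_identical(dim(decode_to_matrix(g0)$values), c(4L, 0L))
})
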