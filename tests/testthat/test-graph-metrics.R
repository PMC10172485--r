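# Weighted network metrics against independent brute-force oracles and
# closed-form examples.

test_that("shortest paths use inverse-weight edge lengths", {
  g2 <- weighted_graph(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(shortest_paths(g2)[1, 2], 2)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.1
  d <- shortest_paths(weighted_graph(w))
  expect_equal(d[1, 3], 4)  # via the middle node; direct edge costs 10

  wc <- matrix(1, 4, 4); diag(wc) <- 0
  expect_true(all(shortest_paths(weighted_graph(wc))[upper.tri(wc)] == 1))
})

test_that("closed-form metric values on small graphs", {
  # complete unit-weight graph: all four properties are exactly 1
  w21 <- matrix(1, 21, 21); diag(w21) <- 0
  nm <- network_properties(weighted_graph(w21))
  expect_identical(c(nm$clu, nm$le, nm$ge, nm$path_length), c(1, 1, 1, 1))

  g2 <- weighted_graph(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(global_efficiency(g2), 0.5)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[2, 3] <- w[3, 2] <- 0.5; w[1, 3] <- w[3, 1] <- 0.1
  expect_equal(characteristic_path_length(weighted_graph(w)), 8 / 3)

  # equal-weight triangle: max-normalized clustering is exactly 1
  wt <- matrix(0.6, 3, 3); diag(wt) <- 0
  expect_equal(clustering_coefficient(weighted_graph(wt), "graph_max"), 1)
  expect_equal(clustering_coefficient(weighted_graph(wt), "none"), 0.6)

  # triangle 0.8/0.8/0.1: node A's normalized triangle intensity is
  # (1 * 1 * 0.125)^(1/3) = 0.5
  wt2 <- matrix(0, 3, 3)
  wt2[1, 2] <- wt2[2, 1] <- 0.8
  wt2[1, 3] <- wt2[3, 1] <- 0.8
  wt2[2, 3] <- wt2[3, 2] <- 0.1
  # every node sees the same triangle, so the mean equals C_A = 0.5
  expect_equal(clustering_coefficient(weighted_graph(wt2), "graph_max"), 0.5,
               tolerance = 1e-12)

  # star graph: every neighbourhood is edgeless, local efficiency 0
  ws <- matrix(0, 5, 5)
  ws[1, 2:5] <- ws[2:5, 1] <- 0.8
  expect_equal(local_efficiency(weighted_graph(ws)), 0)
})

test_that("metrics match brute-force oracles on random graphs", {
  for (seed in 1:100) {
    n <- 5 + seed %% 6
    w <- random_weights(n, seed)
    g <- weighted_graph(w)
    expect_equal(max(abs(shortest_paths(g) - fw_distances(w))), 0,
                 tolerance = 1e-10)
    expect_equal(global_efficiency(g), brute_ge(w), tolerance = 1e-10)
    expect_equal(characteristic_path_length(g), brute_L(w), tolerance = 1e-10)
    expect_equal(clustering_coefficient(g, "graph_max"),
                 brute_clu(w, "graph_max"), tolerance = 1e-10)
    expect_equal(clustering_coefficient(g, "none"),
                 brute_clu(w, "none"), tolerance = 1e-10)
    expect_equal(local_efficiency(g), brute_le(w), tolerance = 1e-10)
  }
})

test_that("shortest paths agree with igraph on random graphs", {
  for (seed in 1:10) {
    w <- random_weights(7, seed)
    gi <- igraph::graph_from_adjacency_matrix(1 / w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    d_ref <- igraph::distances(gi, algorithm = "dijkstra")
    expect_equal(unname(shortest_paths(weighted_graph(w))), unname(d_ref),
                 tolerance = 1e-12)
  }
})

test_that("metric invariants: bounds, permutation, monotonicity, scaling", {
  for (seed in 1:20) {
    w <- random_weights(8, seed)
    g <- weighted_graph(w)
    ge <- global_efficiency(g)
    L <- characteristic_path_length(g)
    expect_lte(ge, 1)
    expect_gte(L, 1)

    # relabeling leaves all four scalars unchanged
    set.seed(seed)
    p <- sample(8)
    gp <- weighted_graph(w[p, p])
    expect_equal(global_efficiency(gp), ge, tolerance = 1e-12)
    expect_equal(characteristic_path_length(gp), L, tolerance = 1e-12)
    expect_equal(clustering_coefficient(gp), clustering_coefficient(g),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(gp), local_efficiency(g),
                 tolerance = 1e-12)

    # raising one edge weight cannot hurt global efficiency or path length
    i <- sample(7, 1); j <- i + 1
    w2 <- w
    w2[i, j] <- w2[j, i] <- min(1, w[i, j] + 0.3)
    expect_gte(global_efficiency(weighted_graph(w2)), ge - 1e-12)
    expect_lte(characteristic_path_length(weighted_graph(w2)), L + 1e-12)

    # edge length 1/w: halving all weights doubles L
    expect_equal(characteristic_path_length(weighted_graph(w / 2)), 2 * L,
                 tolerance = 1e-10)
  }
})

test_that("invalid and degenerate graphs are rejected", {
  asym <- matrix(c(0, 0.2, 0.4, 0), 2)
  expect_error(weighted_graph(asym), "symmetric")
  expect_error(weighted_graph(matrix(c(0, 1.2, 1.2, 0), 2)), "\\[0, 1\\]")

  cm <- make_cm(matrix(c(1, 0.5, 0.5, 1), 2))
  g <- from_coherence(cm)
  expect_equal(unname(g$weights), matrix(c(0, 0.5, 0.5, 0), 2))

  # all-zero off-diagonals: every node isolated, L undefined
  z <- matrix(0, 4, 4)
  expect_error(characteristic_path_length(weighted_graph(z)), "disconnected")

  # two components: unreached pairs excluded with a warning
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.5
  expect_warning(L <- characteristic_path_length(weighted_graph(w)),
                 "excluded")
  expect_equal(L, 2)
})
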