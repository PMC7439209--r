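path3 <- matrix(c(0, 1, 0,
                  1, 0, 1,
                  0, 1, 0), 3, 3, byrow = TRUE)
triangle <- matrix(1, 3, 3) - diag(3)

test_that("shortest path lengths match BFS expectations and handle components", {
  D <- shortest_path_lengths(path3)
  expect_equal(D[1, ], c(0, 1, 2))
  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- 1
  two_comp[3, 4] <- two_comp[4, 3] <- 1
  D2 <- shortest_path_lengths(two_comp)
  expect_true(is.infinite(D2[1, 3]))
  expect_equal(D2[3, 4], 1)
})

test_that("characteristic path length is the harmonic mean of shortest paths", {
  expect_equal(characteristic_path_length(shortest_path_lengths(triangle)), 1)
  # path of 3: pair distances {1,1,2}, harmonic mean 6/5
  expect_equal(characteristic_path_length(shortest_path_lengths(path3)), 1.2)
  empty <- matrix(0, 3, 3)
  expect_equal(characteristic_path_length(shortest_path_lengths(empty)), Inf)
})

test_that("clustering coefficient counts triangle fractions per node", {
  expect_equal(clustering_coefficient(triangle), 1)
  expect_equal(clustering_coefficient(path3), 0)
  # triangle plus a pendant on one vertex: (1 + 1 + 1/3 + 0) / 4
  tp <- matrix(0, 4, 4)
  tp[1, 2] <- tp[1, 3] <- tp[2, 3] <- tp[3, 4] <- 1
  tp <- tp + t(tp); tp[tp > 1] <- 1
  expect_equal(clustering_coefficient(tp), 7 / 12)
})

test_that("efficiencies follow their inverse-distance definitions", {
  expect_equal(global_efficiency(shortest_path_lengths(triangle)), 1)
  expect_equal(global_efficiency(shortest_path_lengths(path3)), 5 / 6)
  expect_equal(global_efficiency(shortest_path_lengths(matrix(0, 3, 3))), 0)
  expect_equal(local_efficiency(triangle), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(local_efficiency(star), 0)
  # nodal efficiency: path of 3 -> center 1, ends (1 + 1/2)/2
  expect_equal(nodal_efficiency(shortest_path_lengths(path3)),
               c(0.75, 1, 0.75))
})

test_that("degree centrality is the binary row sum with the handshake identity", {
  expect_equal(degree_centrality(path3), c(1, 2, 1))
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(degree_centrality(K5), rep(4, 5))
  for (s in 1:5) {
    A <- random_graph(15, 0.3, seed = s)
    expect_equal(sum(degree_centrality(A)), sum(A))
  }
})

test_that("every metric matches its brute-force oracle on random graphs", {
  for (s in 1:25) {
    n <- sample(5:20, 1)
    A <- random_graph(n, runif(1, 0.15, 0.6), seed = 1000 + s)
    D <- shortest_path_lengths(A)
    Do <- oracle_distances(A)
    expect_equal(D, Do)
    expect_equal(global_efficiency(D), oracle_global_efficiency(Do),
                 tolerance = 1e-10)
    expect_equal(characteristic_path_length(D), oracle_lp(Do),
                 tolerance = 1e-10)
    expect_equal(clustering_coefficient(A), oracle_clustering(A),
                 tolerance = 1e-10)
    expect_equal(local_efficiency(A), oracle_local_efficiency(A),
                 tolerance = 1e-10)
    expect_equal(nodal_efficiency(D), oracle_nodal_efficiency(Do),
                 tolerance = 1e-10)
  }
})

test_that("analytic identities hold on arbitrary graphs", {
  for (s in 1:10) {
    A <- random_graph(18, 0.25, seed = 300 + s)
    D <- shortest_path_lengths(A)
    e <- global_efficiency(D)
    if (e > 0) {
      expect_equal(characteristic_path_length(D) * e, 1, tolerance = 1e-12)
    }
    expect_equal(mean(nodal_efficiency(D)), e, tolerance = 1e-12)
  }
})

test_that("rewiring preserves the degree sequence and ensemble size", {
  A <- random_graph(20, 0.3, seed = 77)
  randoms <- rewire_random(A, randomization_config(n_random = 8, seed = 5))
  expect_length(randoms, 8)
  for (R in randoms) {
    expect_equal(rowSums(R), rowSums(A))
    expect_identical(R, t(R))
    expect_equal(unname(diag(R)), rep(0L, 20))
  }
  # determinism under the configured seed
  randoms2 <- rewire_random(A, randomization_config(n_random = 8, seed = 5))
  expect_identical(randoms, randoms2)
  # a triangle is the only graph with its degree sequence
  r3 <- rewire_random(triangle, randomization_config(n_random = 100, seed = 1))
  expect_length(r3, 100)
  for (R in r3) expect_equal(unname(R), unname(triangle))
})

test_that("normalization against matched randoms yields sigma = gamma / lambda", {
  A <- ring_lattice(30, 4)
  D <- shortest_path_lengths(A)
  Lp <- characteristic_path_length(D)
  Cp <- clustering_coefficient(A)
  # self-normalization: ensemble identical to the observed graph
  self <- normalize_and_sigma(Lp, Cp, list(A, A, A))
  expect_equal(self$sigma, 1)
  expect_equal(self$lambda, 1)
  expect_equal(self$gamma, 1)
  # a ring lattice is small-world-like against degree-preserving randoms
  randoms <- rewire_random(A, randomization_config(n_random = 20, seed = 9))
  norm <- normalize_and_sigma(Lp, Cp, randoms)
  expect_gt(norm$sigma, 1)
  expect_equal(norm$sigma, norm$gamma / norm$lambda, tolerance = 1e-12)
})

test_that("metric stacks over sparsity respect efficiency monotonicity", {
  w <- tiny_world()
  nets <- build_hemispheric_networks(w$cohort$subjects[[2]], w$parcellation,
                                     subject_id = "sub-002")
  m <- network_metrics(nets$L)
  g <- m$global[order(m$global$sparsity), ]
  expect_true(all(diff(g$E_global) >= 0))
  expect_true(all(diff(g$Lp) <= 0))
  # identity across the computed stack
  expect_equal(g$Lp * g$E_global, rep(1, nrow(g)), tolerance = 1e-12)
  # handshake at each level
  loc <- m$local
  for (k in unique(loc$sparsity)) {
    n_edges <- sum(nets$L$binaries[[sprintf("%.2f", k)]]) / 2
    expect_equal(sum(loc$degree[loc$sparsity == k]), 2 * n_edges)
  }
})
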