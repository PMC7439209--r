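test_that("jsd matches hand-evaluated and limiting cases", {
  p <- c(0.75, 0.25); attr(p, "grid") <- 1:2
  q <- c(0.25, 0.75); attr(q, "grid") <- 1:2
  # 0.75*log(1.5) + 0.25*log(0.5) evaluated by hand
  expect_equal(jsd(p, q), 0.1308, tolerance = 1e-4)
  expect_equal(jsd(p, p), 0)

  # near-disjoint supports approach log(2); similarity approaches 0.5
  eps <- 1e-12
  a <- c(1 - 26 * eps, rep(eps, 26)); attr(a, "grid") <- 1:27
  b <- c(rep(eps, 26), 1 - 26 * eps); attr(b, "grid") <- 1:27
  expect_equal(jsd(a, b), log(2), tolerance = 1e-9)
  expect_equal(jss(a, b), 0.5, tolerance = 1e-9)

  g1 <- c(0.5, 0.5); attr(g1, "grid") <- c(1, 2)
  g2 <- c(0.5, 0.5); attr(g2, "grid") <- c(1, 3)
  expect_error(jsd(g1, g2), class = "hemimorph_input_error")
})

test_that("jsd agrees with direct formula evaluation on random mesh distributions", {
  for (s in 1:40) {
    p <- random_density(27, seed = s)
    q <- random_density(27, seed = s + 1000)
    expect_equal(jsd(p, q), oracle_jsd(p, q), tolerance = 1e-12)
    # metric-like behavior
    expect_gte(jsd(p, q), 0)
    expect_lte(jsd(p, q), log(2) + 1e-12)
    expect_equal(jsd(p, q), jsd(q, p))
    expect_equal(jss(p, q), jss(q, p), tolerance = 1e-12)
    expect_equal(jss(p, q), exp(-jsd(p, q)))
  }
  # the vectorized pairwise kernel agrees with the scalar route
  P <- rbind(random_density(27, 1), random_density(27, 2),
             random_density(27, 3))
  D <- hemimorph:::.jsd_pairwise(P)
  for (i in 1:2) for (j in (i + 1):3) {
    pi <- P[i, ]; attr(pi, "grid") <- 1:27
    pj <- P[j, ]; attr(pj, "grid") <- 1:27
    expect_equal(D[i, j], jsd(pi, pj), tolerance = 1e-12)
  }
})

test_that("weight matrices are symmetric, zero-diagonal similarity matrices", {
  P <- rbind(random_density(27, 5), random_density(27, 6),
             random_density(27, 7))
  rownames(P) <- c("10", "11", "12")
  W <- build_weight_matrix(P)
  expect_equal(dim(W), c(3, 3))
  expect_identical(W, t(W))
  expect_equal(unname(diag(W)), rep(0, 3))
  off <- W[upper.tri(W)]
  expect_true(all(off > 0 & off <= 1))
  # duplicated densities are maximally similar
  W2 <- build_weight_matrix(P[c(1, 1, 1), ])
  expect_equal(unname(W2[upper.tri(W2)]), rep(1, 3))
  expect_error(build_weight_matrix(P, expected_nodes = 5),
               class = "hemimorph_input_error")
})

test_that("binarization keeps the exact top-K edges with nesting across levels", {
  # 5 nodes, distinct weights, K = 0.4 -> the 4 strongest edges, by brute force
  set.seed(31)
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- sample(seq(0.1, 1, length.out = 10))
  W <- W + t(W)
  A <- binarize(W, 0.4)[[1]]
  expect_equal(sum(A) / 2, 4)
  ut <- which(upper.tri(W))
  top4 <- ut[order(W[ut], decreasing = TRUE)[1:4]]
  expect_true(all(A[top4] == 1))

  expect_equal(sum(binarize(W, 0.999)[[1]]) / 2, 9)  # near-complete

  grid <- sparsity_grid()
  set.seed(32)
  W <- matrix(runif(40 * 40), 40, 40); W <- (W + t(W)) / 2; diag(W) <- 0
  bins <- binarize(W, grid)
  counts <- vapply(bins, function(B) sum(B) / 2, numeric(1))
  expect_equal(unname(counts), floor(grid * 40 * 39 / 2))
  for (k in seq_len(length(bins) - 1)) {
    expect_true(all(bins[[k]] <= bins[[k + 1]]))  # nested edge sets
  }
  expect_error(binarize(matrix(c(0, 1e-3, 1e-3, 0), 2), 0.1),
               "zero edges", class = "hemimorph_input_error")
})

test_that("the sparsity grid defaults to 14 levels from 0.10 to 0.36", {
  g <- sparsity_grid()
  expect_length(g, 14)
  expect_equal(g[1], 0.10)
  expect_equal(g[14], 0.36)
  expect_equal(unique(round(diff(g), 10)), 0.02)
  expect_error(sparsity_grid(0.5, 0.2, 0.02), class = "hemimorph_config_error")
})

test_that("hemispheric networks carry the subregion node sets of their hemisphere", {
  w <- tiny_world()
  nets <- build_hemispheric_networks(w$cohort$subjects[[1]], w$parcellation,
                                     subject_id = "sub-001")
  expect_named(nets, c("L", "R"))
  for (h in c("L", "R")) {
    net <- nets[[h]]
    expect_s3_class(net, "hemimorph_network")
    expect_equal(dim(net$weights), c(32, 32))
    expect_equal(length(net$binaries), 14)
    expect_equal(net$node_ids,
                 w$parcellation$subregions$subregion_id[
                   w$parcellation$subregions$hemisphere == h])
    expect_identical(net$weights, t(net$weights))
    expect_true(all(net$weights[upper.tri(net$weights)] > 0))
  }
})
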