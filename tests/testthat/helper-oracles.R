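# Independent brute-force oracles, deliberately written against the plain
# formulas (loops, Floyd-Warshall) and never sharing code with the package.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

oracle_global_efficiency <- function(D) {
  n <- nrow(D)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    }
  }
  s / (n * (n - 1))
}

oracle_lp <- function(D) {
  e <- oracle_global_efficiency(D)
  if (e == 0) Inf else 1 / e
}

oracle_nodal_efficiency <- function(D) {
  n <- nrow(D)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    }
    s / (n - 1)
  })
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && A[nb[a], nb[b]] == 1) e <- e + 1
      }
    }
    cc[i] <- 2 * e / (k * (k - 1))
  }
  mean(cc)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    el[i] <- oracle_global_efficiency(oracle_distances(sub))
  }
  mean(el)
}

# Direct elementwise evaluation of the divergence definition.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) s <- s + 0.5 * p[k] * log(p[k] / m[k])
    if (q[k] > 0) s <- s + 0.5 * q[k] * log(q[k] / m[k])
  }
  s
}

# Two-loop regional integration: region mean at each sparsity, then mean
# over sparsity levels.
oracle_integrate_local <- function(values, region_of, levels) {
  regions <- unique(region_of[match(unique(values$node), names(region_of))])
  out <- sapply(sort(regions), function(r) {
    nodes <- names(region_of)[region_of == r]
    per_level <- sapply(levels, function(s) {
      v <- values$value[values$sparsity == s & values$node %in% as.integer(nodes)]
      mean(v)
    })
    mean(per_level)
  })
  out
}
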