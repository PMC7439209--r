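#' Configure random-network normalization
#'
#' Normalized path length and clustering divide the observed values by the
#' mean over an ensemble of degree-preserving random networks obtained by
#' repeated double-edge swaps (edge shuffling that preserves the number of
#' nodes, the number of edges, and every node's degree).
#'
#' @param n_random ensemble size (default 100).
#' @param swaps_per_edge attempted swaps per edge in each rewiring
#'   (default 10).
#' @param seed integer seed for the rewiring RNG.
#' @return a `hemimorph_randomization_config` list.
#' @export
randomization_config <- function(n_random = 100L, swaps_per_edge = 10L,
                                 seed = 1L) {
  if (!is_count(n_random)) stop_config("`n_random` must be a positive integer")
  if (!is_count(swaps_per_edge)) stop_config("`swaps_per_edge` must be a positive integer")
  structure(
    list(n_random = as.integer(n_random),
         swaps_per_edge = as.integer(swaps_per_edge),
         seed = as.integer(seed)),
    class = "hemimorph_randomization_config"
  )
}

check_binary <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_input("adjacency matrix must be square")
  if (!all(A == 0 | A == 1)) stop_input("adjacency matrix must be 0/1")
  if (any(A != t(A))) stop_input("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop_input("adjacency matrix must have zero diagonal")
  storage.mode(A) <- "integer"
  A
}

#' Shortest path lengths of a binary network
#'
#' Unweighted breadth-first distances between all node pairs; unreachable
#' pairs are `Inf` and the diagonal is 0.
#'
#' @param A symmetric 0/1 adjacency matrix with zero diagonal.
#' @return numeric distance matrix.
#' @export
shortest_path_lengths <- function(A) {
  A <- check_binary(A)
  D <- .bfs_distances(A)
  D[D < 0] <- Inf
  storage.mode(D) <- "double"
  D
}

#' Characteristic path length (harmonic mean of shortest paths)
#'
#' \deqn{L_p = \left[\frac{\sum_{i \ne j} L_{ij}^{-1}}{N (N - 1)}\right]^{-1}}
#' with \eqn{1/\infty = 0}, so the value is finite on any graph with at
#' least one connected pair and `Inf` on an empty graph. By construction
#' `characteristic_path_length(D) * global_efficiency(D) == 1`.
#'
#' @param D distance matrix from [shortest_path_lengths()].
#' @return scalar path length.
#' @export
characteristic_path_length <- function(D) {
  e <- global_efficiency(D)
  if (e == 0) Inf else 1 / e
}

#' Global efficiency (mean inverse shortest path length)
#'
#' @param D distance matrix from [shortest_path_lengths()].
#' @return scalar in \[0, 1\].
#' @export
global_efficiency <- function(D) {
  n <- nrow(D)
  if (is.null(n) || n < 2) stop_input("need at least 2 nodes")
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Per node, the mean inverse shortest path length to every other node; the
#' node-average of this vector equals [global_efficiency()].
#'
#' @param D distance matrix from [shortest_path_lengths()].
#' @return numeric vector, one value per node.
#' @export
nodal_efficiency <- function(D) {
  n <- nrow(D)
  if (is.null(n) || n < 2) stop_input("need at least 2 nodes")
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Clustering coefficient
#'
#' Mean over nodes of the fraction of closed triangles around each node,
#' \eqn{2 E_i / (k_i (k_i - 1))}; nodes with degree below 2 contribute 0.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(A) {
  mean(.local_clustering(check_binary(A)))
}

#' Local efficiency
#'
#' Node-average of the global efficiency of each node's neighbor-induced
#' subgraph (the node itself removed); degree below 2 contributes 0.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(A) {
  mean(.local_efficiency_nodes(check_binary(A)))
}

#' Degree centrality
#'
#' Number of edges incident on each node (binary row sums).
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @return integer vector, one value per node.
#' @export
degree_centrality <- function(A) {
  A <- check_binary(A)
  as.integer(rowSums(A))
}

#' Degree-preserving random networks
#'
#' Generates an ensemble of random networks by repeated double-edge swaps
#' (`swaps_per_edge * E` attempted swaps each), exactly preserving every
#' node's degree. The rewiring consumes R's RNG stream, so results are
#' reproducible under the configured seed.
#'
#' @param A symmetric 0/1 adjacency matrix with at least 2 edges.
#' @param config a [randomization_config()].
#' @return list of adjacency matrices of length `config$n_random`.
#' @export
rewire_random <- function(A, config = randomization_config()) {
  A <- check_binary(A)
  n_edges <- sum(A) / 2
  if (n_edges < 2) stop_input("need at least 2 edges to rewire")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  niter <- config$swaps_per_edge * n_edges
  with_seed(config$seed, {
    lapply(seq_len(config$n_random), function(k) {
      r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
      R <- igraph::as_adjacency_matrix(r, sparse = FALSE)
      storage.mode(R) <- "integer"
      R
    })
  })
}

#' Random-network normalization and small-worldness
#'
#' \eqn{\lambda = L_p / L_{ran}}, \eqn{\gamma = C_p / C_{ran}} and
#' \eqn{\sigma = \gamma / \lambda}, where \eqn{L_{ran}} and \eqn{C_{ran}}
#' are ensemble means over the supplied random networks.
#'
#' @param Lp,Cp observed characteristic path length and clustering
#'   coefficient.
#' @param randoms list of random adjacency matrices from [rewire_random()].
#' @return tibble with columns `L_ran`, `C_ran`, `lambda`, `gamma`, `sigma`
#'   and logical `degenerate` flag (`TRUE` when `C_ran` is 0 and gamma is
#'   undefined).
#' @export
normalize_and_sigma <- function(Lp, Cp, randoms) {
  if (!length(randoms)) stop_input("`randoms` must be a nonempty list")
  ran <- vapply(randoms, function(R) {
    D <- shortest_path_lengths(R)
    c(characteristic_path_length(D), clustering_coefficient(R))
  }, numeric(2))
  L_ran <- mean(ran[1, ])
  C_ran <- mean(ran[2, ])
  degenerate <- C_ran == 0
  lambda <- Lp / L_ran
  gamma <- if (degenerate) NA_real_ else Cp / C_ran
  tibble(L_ran = L_ran, C_ran = C_ran, lambda = lambda, gamma = gamma,
         sigma = gamma / lambda, degenerate = degenerate)
}

#' Global and local graph metrics of one binary network
#'
#' `global_metrics()` returns one row with the characteristic path length,
#' clustering coefficient, efficiencies, and — when a randomization config
#' is supplied — the random-network means and normalized metrics.
#' `local_metrics()` returns the per-node degree and nodal efficiency.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @param randomization optional [randomization_config()].
#' @return a tibble.
#' @export
global_metrics <- function(A, randomization = NULL) {
  A <- check_binary(A)
  D <- shortest_path_lengths(A)
  Lp <- characteristic_path_length(D)
  Cp <- clustering_coefficient(A)
  out <- tibble(
    Lp = Lp, Cp = Cp,
    E_global = global_efficiency(D),
    E_local = local_efficiency(A)
  )
  if (!is.null(randomization)) {
    randoms <- rewire_random(A, randomization)
    # one BFS pass per random serves Lp, E_global and the normalization
    ran <- vapply(randoms, function(R) {
      DR <- shortest_path_lengths(R)
      c(characteristic_path_length(DR), mean(.local_clustering(R)),
        global_efficiency(DR), mean(.local_efficiency_nodes(R)))
    }, numeric(4))
    out$L_ran <- mean(ran[1, ])
    out$C_ran <- mean(ran[2, ])
    out$lambda <- Lp / out$L_ran
    out$gamma <- if (out$C_ran == 0) NA_real_ else Cp / out$C_ran
    out$sigma <- out$gamma / out$lambda
    out$E_global_ran <- mean(ran[3, ])
    out$E_local_ran <- mean(ran[4, ])
  }
  out
}

#' @rdname global_metrics
#' @param node_ids optional node identifiers for the output.
#' @export
local_metrics <- function(A, node_ids = NULL) {
  A <- check_binary(A)
  D <- shortest_path_lengths(A)
  tibble(
    node = node_ids %||% seq_len(nrow(A)),
    degree = degree_centrality(A),
    E_nodal = nodal_efficiency(D)
  )
}

#' Metrics of one hemispheric network across its sparsity stack
#'
#' Computes [global_metrics()] and [local_metrics()] on each binary matrix
#' of a `hemimorph_network`. Random-network seeds are derived per sparsity
#' level from `randomization$seed` so levels are independent and
#' reproducible.
#'
#' @param network a `hemimorph_network` from [build_hemispheric_networks()].
#' @param randomization optional [randomization_config()] for normalized
#'   global metrics.
#' @return list of tibbles `global` (one row per sparsity) and `local` (one
#'   row per sparsity x node).
#' @export
network_metrics <- function(network, randomization = NULL) {
  stopifnot(inherits(network, "hemimorph_network"))
  if (is.null(network$binaries)) stop_input("network has no binary stack")
  levels <- names(network$binaries)
  res <- lapply(seq_along(levels), function(k) {
    A <- network$binaries[[k]]
    rcfg <- if (is.null(randomization)) NULL else {
      randomization_config(
        n_random = randomization$n_random,
        swaps_per_edge = randomization$swaps_per_edge,
        seed = derive_seed(randomization$seed, 7L, k)
      )
    }
    g <- global_metrics(A, rcfg)
    g$sparsity <- as.numeric(levels[k])
    l <- local_metrics(A, node_ids = network$node_ids)
    l$sparsity <- as.numeric(levels[k])
    list(global = g, local = l)
  })
  list(
    global = dplyr::bind_rows(lapply(res, `[[`, "global")),
    local = dplyr::bind_rows(lapply(res, `[[`, "local"))
  )
}
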