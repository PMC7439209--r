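#' Sparsity grid for network binarization
#'
#' Sparsity is the fraction of realized edges out of all possible node
#' pairs. The default grid is 0.10 to 0.36 in steps of 0.02 (14 levels); the
#' sparsity-integrated metrics average over exactly this set.
#'
#' @param from,to,by grid limits and step.
#' @return numeric vector of sparsity fractions.
#' @export
#' @examples
#' length(sparsity_grid())  # 14
sparsity_grid <- function(from = 0.10, to = 0.36, by = 0.02) {
  if (!is_number(from) || !is_number(to) || !is_number(by) ||
      from > to || by <= 0) {
    stop_config("sparsity grid needs from <= to and a positive step")
  }
  values <- seq(from, to, by = by)
  if (any(values <= 0) || any(values >= 1) || any(diff(values) <= 0)) {
    stop_config("sparsity values must be strictly increasing fractions in (0, 1)")
  }
  round(values, 10)
}

#' Jensen-Shannon divergence and similarity between two regional densities
#'
#' `jsd()` is the symmetrized divergence
#' \deqn{JSD(p, q) = \frac12 \sum_x p \log\frac{p}{m} +
#'       \frac12 \sum_x q \log\frac{q}{m}, \quad m = (p + q) / 2,}
#' computed with natural logarithms on the shared discrete mesh, so it lies
#' in \eqn{[0, \log 2]}. `jss()` is the similarity transform
#' \eqn{\exp(-JSD)}, equal to 1 exactly when the two distributions agree on
#' the mesh.
#'
#' @param p,q probability vectors from [estimate_density()] (or any two
#'   distributions on the same mesh).
#' @return a single divergence (nats) or similarity value.
#' @export
jsd <- function(p, q) {
  check_shared_grid(p, q)
  m <- (p + q) / 2
  d <- 0.5 * sum(ifelse(p > 0, p * log(p / m), 0)) +
    0.5 * sum(ifelse(q > 0, q * log(q / m), 0))
  max(d, 0)
}

#' @rdname jsd
#' @export
jss <- function(p, q) exp(-jsd(p, q))

check_shared_grid <- function(p, q) {
  if (length(p) != length(q)) stop_input("densities have different mesh sizes")
  gp <- attr(p, "grid")
  gq <- attr(q, "grid")
  if (!is.null(gp) && !is.null(gq) && !isTRUE(all.equal(gp, gq))) {
    stop_input("densities estimated on different meshes")
  }
  invisible(TRUE)
}

#' Build one hemisphere's similarity weight matrix
#'
#' All pairwise Jensen-Shannon similarities between the hemisphere's
#' subregion densities, with the diagonal forced to 0 (no self-loops).
#'
#' @param densities numeric matrix (subregions x mesh points) of densities
#'   sharing one mesh, e.g. the rows of [subject_densities()] belonging to
#'   one hemisphere.
#' @param expected_nodes if non-NULL, the required number of rows.
#' @return symmetric similarity matrix with zero diagonal, dimnames taken
#'   from the density row names.
#' @export
build_weight_matrix <- function(densities, expected_nodes = NULL) {
  densities <- as.matrix(densities)
  if (!is.null(expected_nodes) && nrow(densities) != expected_nodes) {
    stop_input(sprintf("expected %d densities, got %d",
                       expected_nodes, nrow(densities)))
  }
  if (nrow(densities) < 2) stop_input("need at least 2 densities")
  W <- exp(-.jsd_pairwise(densities))
  diag(W) <- 0
  dimnames(W) <- list(rownames(densities), rownames(densities))
  W
}

#' Binarize a weight matrix over a sparsity grid
#'
#' At sparsity `K` the `floor(K * N * (N - 1) / 2)` largest-weight edges are
#' kept. Ties are broken deterministically by smaller node id, then smaller
#' partner id, which makes the binary edge sets exactly nested across
#' increasing sparsity.
#'
#' @param weights symmetric weight matrix with zero diagonal.
#' @param grid sparsity levels from [sparsity_grid()].
#' @return named list (one element per sparsity level, names formatted to
#'   2 decimals) of integer 0/1 matrices.
#' @export
binarize <- function(weights, grid = sparsity_grid()) {
  n <- nrow(weights)
  if (n != ncol(weights) || max(abs(weights - t(weights))) > 1e-10) {
    stop_input("`weights` must be a symmetric square matrix")
  }
  ut <- which(upper.tri(weights))
  i <- row(weights)[ut]
  j <- col(weights)[ut]
  w <- weights[ut]
  ord <- order(-w, i, j)
  i <- i[ord]; j <- j[ord]
  n_pairs <- length(ut)
  out <- lapply(grid, function(K) {
    m <- floor(K * n_pairs)
    if (m < 1) stop_input(sprintf("sparsity %.3f yields zero edges", K))
    A <- matrix(0L, n, n, dimnames = dimnames(weights))
    keep <- seq_len(m)
    A[cbind(i[keep], j[keep])] <- 1L
    A[cbind(j[keep], i[keep])] <- 1L
    A
  })
  names(out) <- sprintf("%.2f", grid)
  out
}

#' Construct a subject's two hemispheric morphological networks
#'
#' End-to-end per-subject construction: shared-mesh density estimation,
#' Jensen-Shannon similarity weight matrices (one per hemisphere), and
#' sparsity-thresholded binary stacks.
#'
#' @param subject vertex table with thickness.
#' @param parcellation `hemimorph_parcellation` of the subject's template.
#' @param density_cfg a [density_config()].
#' @param sparsity levels from [sparsity_grid()]; `NULL` skips binarization.
#' @param subject_id identifier carried into the result.
#' @return named list (`L`, `R`) of `hemimorph_network` objects, each with
#'   `subject_id`, `hemisphere`, `node_ids`, `weights`, `binaries`.
#' @export
build_hemispheric_networks <- function(subject, parcellation,
                                       density_cfg = density_config(),
                                       sparsity = sparsity_grid(),
                                       subject_id = "subject") {
  dens <- subject_densities(subject, parcellation, density_cfg)
  subs <- parcellation$subregions
  out <- lapply(c(L = "L", R = "R"), function(h) {
    ids <- subs$subregion_id[subs$hemisphere == h]
    W <- build_weight_matrix(dens[as.character(ids), , drop = FALSE])
    structure(
      list(
        subject_id = subject_id,
        hemisphere = h,
        node_ids = ids,
        weights = W,
        binaries = if (is.null(sparsity)) NULL else binarize(W, sparsity)
      ),
      class = "hemimorph_network"
    )
  })
  out
}
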