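#' Configure regional thickness density estimation
#'
#' Each subregion's thickness distribution is a Gaussian-kernel density
#' evaluated on a fixed mesh of `mesh_points` thickness values (default 27)
#' shared by every subregion of a subject. The shared mesh is what makes the
#' pointwise mixture inside the Jensen-Shannon divergence well defined.
#'
#' @param mesh_points number of mesh points (>= 3; default 27).
#' @param bandwidth fixed kernel bandwidth in mm, or `NULL` (default) for
#'   Silverman's rule on the subject's pooled thickness values.
#' @param grid_pad_bandwidths mesh padding beyond the pooled range, in
#'   bandwidth units (default 3).
#' @param floor_eps probability floor applied before renormalization
#'   (default 1e-12) so divergence logarithms stay finite.
#' @return a `hemimorph_density_config` list.
#' @export
density_config <- function(mesh_points = 27L, bandwidth = NULL,
                           grid_pad_bandwidths = 3, floor_eps = 1e-12) {
  if (!is_count(mesh_points, 3)) stop_config("`mesh_points` must be an integer >= 3")
  if (!is.null(bandwidth) && (!is_number(bandwidth) || bandwidth <= 0)) {
    stop_config("`bandwidth` must be NULL or a positive number (mm)")
  }
  if (!is_number(grid_pad_bandwidths) || grid_pad_bandwidths < 0) {
    stop_config("`grid_pad_bandwidths` must be non-negative")
  }
  if (!is_number(floor_eps) || floor_eps <= 0 || floor_eps >= 1e-3) {
    stop_config("`floor_eps` must be a small positive probability")
  }
  structure(
    list(mesh_points = as.integer(mesh_points), bandwidth = bandwidth,
         grid_pad_bandwidths = grid_pad_bandwidths, floor_eps = floor_eps),
    class = "hemimorph_density_config"
  )
}

#' Build a subject's shared thickness mesh
#'
#' Equally spaced mesh spanning the subject's pooled thickness range padded
#' by `grid_pad_bandwidths` bandwidths on each side.
#'
#' @param thickness pooled thickness values of one subject.
#' @param config a [density_config()].
#' @return numeric mesh with attribute `bandwidth`.
#' @export
make_grid <- function(thickness, config = density_config()) {
  thickness <- thickness[!is.na(thickness)]
  if (length(unique(thickness)) < 2) {
    stop_input("degenerate thickness sample: need at least 2 distinct values")
  }
  h <- config$bandwidth %||% bw.nrd0(thickness)
  pad <- config$grid_pad_bandwidths * h
  grid <- seq(min(thickness) - pad, max(thickness) + pad,
              length.out = config$mesh_points)
  attr(grid, "bandwidth") <- h
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate a regional thickness distribution on a mesh
#'
#' Gaussian-kernel density of `values` evaluated at the mesh points, floored
#' at `floor_eps`, and renormalized to sum to 1 — a discrete probability
#' distribution on the shared mesh (with a uniform mesh, quadrature weights
#' cancel in the divergence, so plain masses are used throughout).
#'
#' @param values thickness sample of one subregion (>= 2 values).
#' @param grid mesh from [make_grid()].
#' @param bandwidth kernel bandwidth; defaults to the mesh's own.
#' @param floor_eps probability floor (default 1e-12).
#' @return numeric probability vector of `length(grid)` with attribute
#'   `grid`.
#' @export
estimate_density <- function(values, grid,
                             bandwidth = attr(grid, "bandwidth"),
                             floor_eps = 1e-12) {
  if (length(values) < 2) stop_input("need at least 2 thickness values")
  if (!is_number(bandwidth) || bandwidth <= 0) {
    stop_input("`bandwidth` must be positive")
  }
  mass <- colSums(dnorm(outer(values, as.numeric(grid), "-") / bandwidth))
  mass <- mass / sum(mass)
  mass <- pmax(mass, floor_eps)
  mass <- mass / sum(mass)
  # keep the floor after renormalization; the sum stays 1 within 1e-9
  mass <- pmax(mass, floor_eps)
  attr(mass, "grid") <- as.numeric(grid)
  mass
}

#' Estimate all subregion densities of one subject
#'
#' Vectorized over vertices: evaluates the Gaussian kernel for every
#' (vertex, mesh point) pair once and aggregates by subregion, which is
#' algebraically identical to calling [estimate_density()] per subregion on
#' the shared mesh.
#'
#' @param subject vertex table with thickness.
#' @param parcellation a `hemimorph_parcellation` for the subject's template.
#' @param config a [density_config()].
#' @return numeric matrix (subregions x mesh points), rows ordered and named
#'   by subregion id, with attributes `grid` and `bandwidth`.
#' @export
subject_densities <- function(subject, parcellation,
                              config = density_config()) {
  grid <- make_grid(subject$thickness, config)
  h <- attr(grid, "bandwidth")
  assign <- parcellation$vertex$subregion_id[
    match(subject$vertex_id, parcellation$vertex$vertex_id)]
  if (anyNA(assign)) stop_input("subject vertices missing from parcellation")
  n_sub <- max(parcellation$subregions$subregion_id)
  mass <- .kde_rowsum(subject$thickness, as.integer(assign), n_sub,
                      as.numeric(grid), h)
  present <- sort(unique(assign))
  mass <- mass[present, , drop = FALSE]
  mass <- mass / rowSums(mass)
  mass <- pmax(mass, config$floor_eps)
  mass <- mass / rowSums(mass)
  mass <- pmax(mass, config$floor_eps)
  rownames(mass) <- sort(unique(assign))
  if (nrow(mass) != n_sub) {
    stop_input("some subregions received no vertices from this subject")
  }
  attr(mass, "grid") <- as.numeric(grid)
  attr(mass, "bandwidth") <- h
  mass
}
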