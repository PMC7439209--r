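#' Integrate a global metric over the sparsity grid
#'
#' The sparsity-integrated metric is the arithmetic mean of the metric over
#' the grid levels, removing the dependence on any single threshold.
#'
#' @param values numeric vector, one metric value per grid level (in grid
#'   order).
#' @param grid the sparsity grid the values were computed on.
#' @return scalar integrated value.
#' @export
#' @examples
#' integrate_global(sparsity_grid(), sparsity_grid())  # 0.23
integrate_global <- function(values, grid = sparsity_grid()) {
  if (length(values) != length(grid) || anyNA(values)) {
    stop_input("need one non-missing value per sparsity level")
  }
  mean(values)
}

#' Integrate local metrics to anatomical regions
#'
#' At each sparsity level the metric is averaged over the subregions of each
#' anatomical region; the region values are then averaged over the sparsity
#' levels.
#'
#' @param values tibble with columns `node` (subregion id), `sparsity`, and
#'   `value`.
#' @param parcellation a `hemimorph_parcellation` supplying the
#'   subregion-to-region map.
#' @param grid the sparsity grid; every (region, level) cell must be
#'   populated.
#' @return tibble with columns `region`, `hemisphere`, `value`.
#' @export
integrate_local <- function(values, parcellation, grid = sparsity_grid()) {
  subs <- parcellation$subregions
  idx <- match(values$node, subs$subregion_id)
  if (anyNA(idx)) stop_input("values reference unknown subregion ids")
  df <- tibble(
    region = subs$region[idx],
    hemisphere = subs$hemisphere[idx],
    sparsity = values$sparsity,
    value = values$value
  )
  per_level <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$hemisphere, .data$sparsity),
    value = mean(.data$value), .groups = "drop"
  )
  counts <- dplyr::count(per_level, .data$region, .data$hemisphere)
  if (any(counts$n != length(grid))) {
    stop_input("missing sparsity levels for some regions")
  }
  dplyr::summarise(
    dplyr::group_by(per_level, .data$region, .data$hemisphere),
    value = mean(.data$value), .groups = "drop"
  )
}

#' Hemispheric asymmetry index
#'
#' \deqn{AI(M) = 100 \times 2 \times \frac{M_L - M_R}{M_L + M_R}}
#' Positive values indicate leftward asymmetry, negative values rightward;
#' swapping the hemispheres negates the index. Records with
#' \eqn{M_L + M_R = 0} are undefined and returned as `NA`.
#'
#' @param m_left,m_right integrated metric values for the left and right
#'   hemispheric network (vectorized).
#' @return numeric asymmetry index in \[-200, 200\] for positive metrics.
#' @export
#' @examples
#' asymmetry_index(3, 1)  # 100
asymmetry_index <- function(m_left, m_right) {
  s <- m_left + m_right
  out <- 100 * 2 * (m_left - m_right) / s
  undef <- !is.na(s) & s == 0
  if (any(undef)) {
    warning(sprintf("%d asymmetry record(s) undefined (M_L + M_R = 0)",
                    sum(undef)))
    out[undef] <- NA_real_
  }
  out
}

#' Integrate one subject's metrics and derive asymmetry indexes
#'
#' `integrate_subject_metrics()` turns the per-sparsity metric tables of the
#' two hemispheric networks into sparsity-integrated global metrics (per
#' hemisphere) and region-level local metrics. `subject_asymmetry()` then
#' pairs the hemispheres — homologous regions matched by shared anatomical
#' label — and computes the asymmetry index of every metric.
#'
#' @param metrics named list (`L`, `R`) of [network_metrics()] results.
#' @param parcellation the subject's `hemimorph_parcellation`.
#' @param grid the sparsity grid used.
#' @param global_metrics which global metric columns to integrate.
#' @return `integrate_subject_metrics()`: list of tibbles `global`
#'   (hemisphere, metric, value) and `local` (hemisphere, region, metric,
#'   value). `subject_asymmetry()`: tibble (scope, metric, region, AI).
#' @export
integrate_subject_metrics <- function(metrics, parcellation,
                                      grid = sparsity_grid(),
                                      global_metrics = c("Cp", "Lp", "sigma",
                                                         "E_global",
                                                         "E_local")) {
  stopifnot(all(c("L", "R") %in% names(metrics)))
  glb <- dplyr::bind_rows(lapply(c("L", "R"), function(h) {
    g <- metrics[[h]]$global
    g <- g[order(g$sparsity), , drop = FALSE]
    avail <- intersect(global_metrics, names(g))
    tibble(
      hemisphere = h,
      metric = avail,
      value = vapply(avail, function(m) integrate_global(g[[m]], grid),
                     numeric(1))
    )
  }))
  loc <- dplyr::bind_rows(lapply(c("L", "R"), function(h) {
    l <- metrics[[h]]$local
    dplyr::bind_rows(lapply(c(degree = "degree", E_nodal = "E_nodal"),
                            function(m) {
      res <- integrate_local(
        tibble(node = l$node, sparsity = l$sparsity, value = l[[m]]),
        parcellation, grid
      )
      tibble(hemisphere = h, region = res$region, metric = m,
             value = res$value)
    }))
  }))
  loc <- loc[loc$hemisphere == "L" | loc$hemisphere == "R", ]
  list(global = glb, local = loc)
}

#' @rdname integrate_subject_metrics
#' @param integrated output of `integrate_subject_metrics()`.
#' @export
subject_asymmetry <- function(integrated) {
  g <- tidyr::pivot_wider(integrated$global, names_from = "hemisphere",
                          values_from = "value")
  global_ai <- tibble(
    scope = "global", metric = g$metric, region = NA_character_,
    AI = asymmetry_index(g$L, g$R)
  )
  l <- tidyr::pivot_wider(integrated$local, names_from = "hemisphere",
                          values_from = "value")
  if (anyNA(l$L) || anyNA(l$R)) {
    stop_input("homologous pairing incomplete: some regions present in one hemisphere only")
  }
  local_ai <- tibble(
    scope = "region", metric = l$metric, region = l$region,
    AI = asymmetry_index(l$L, l$R)
  )
  dplyr::bind_rows(global_ai, local_ai)
}
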