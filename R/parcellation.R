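#' Allocate subregion counts to anatomical regions
#'
#' Proportional allocation with a largest-remainder correction: each region
#' receives `max(1, round(size / (hemisphere total / target)))` clusters and
#' the counts are then adjusted, one at a time in order of descending
#' (ascending) fractional remainder, until they sum exactly to `target`.
#' Within the unadjusted regions the allocation is monotone in region size.
#'
#' @param region_sizes named integer vector of vertex counts per region (one
#'   hemisphere).
#' @param target total number of subregions for the hemisphere.
#' @param size_floor minimum vertices a subregion must be able to hold
#'   (default 30).
#' @return named integer vector of cluster counts summing to `target`.
#' @export
#' @examples
#' allocate_cluster_counts(c(A = 298), target = 2)
allocate_cluster_counts <- function(region_sizes, target,
                                    size_floor = MIN_SUBREGION_VERTICES) {
  if (!is_count(target) || target < length(region_sizes)) {
    stop_config("`target` must be an integer >= number of regions")
  }
  total <- sum(region_sizes)
  quota <- region_sizes * target / total
  counts <- pmax(1L, as.integer(round(quota)))
  remainder <- quota - counts
  # largest-remainder adjustment toward the exact hemisphere total
  while (sum(counts) != target) {
    if (sum(counts) < target) {
      i <- order(remainder, decreasing = TRUE)[1]
      counts[i] <- counts[i] + 1L
      remainder[i] <- remainder[i] - 1
    } else {
      elig <- which(counts > 1L)
      if (!length(elig)) stop_config("cannot reduce allocation below 1 per region")
      i <- elig[order(remainder[elig])[1]]
      counts[i] <- counts[i] - 1L
      remainder[i] <- remainder[i] + 1
    }
  }
  too_small <- region_sizes < counts * size_floor
  if (any(too_small)) {
    stop_config(sprintf(
      "region(s) too small for allocation at size floor %d: %s",
      size_floor,
      paste(names(region_sizes)[too_small], collapse = ", ")
    ))
  }
  counts
}

#' Upsample an anatomical parcellation into similar-size subregions
#'
#' Runs k-means independently on the sphere coordinates of each anatomical
#' region (preserving anatomical boundaries by construction), with
#' farthest-point seeding from a seeded RNG, Lloyd iterations capped at 100,
#' and ties broken by the lowest vertex id. Subregion ids are numbered
#' hemisphere-major (all left subregions first), then region-major in
#' canonical label order.
#'
#' @param template vertex table (thickness not required).
#' @param target_per_hemisphere subregions per hemisphere (default 256, for
#'   the 512-node scheme).
#' @param seed integer seed for the k-means initialization.
#' @param size_floor minimum subregion size passed to
#'   [allocate_cluster_counts()].
#' @return a `hemimorph_parcellation`: list with `vertex` (tibble vertex_id,
#'   subregion_id) and `subregions` (tibble subregion_id, region, hemisphere,
#'   n_vertices).
#' @export
upsample_parcellation <- function(template, target_per_hemisphere = 256L,
                                  seed = 1L,
                                  size_floor = MIN_SUBREGION_VERTICES) {
  vert_assign <- integer(nrow(template))
  sub_rows <- list()
  next_id <- 1L
  for (h in c("L", "R")) {
    hsel <- template$hemisphere == h
    regions <- unique(template$region[hsel])
    canonical <- c(aal_cortical_regions(),
                   sort(setdiff(regions, aal_cortical_regions())))
    regions <- intersect(canonical, regions)
    sizes <- vapply(regions, function(r) sum(hsel & template$region == r),
                    integer(1))
    counts <- allocate_cluster_counts(sizes, target_per_hemisphere,
                                      size_floor = size_floor)
    for (ri in seq_along(regions)) {
      idx <- which(hsel & template$region == regions[ri])
      k <- counts[ri]
      # seed depends on the region only, not the hemisphere: mirrored
      # hemispheres then receive mirror-identical subclusters, keeping the
      # whole pipeline exactly equivariant under L/R relabeling
      cl <- region_kmeans(as.matrix(template[idx, c("x", "y", "z")]), k,
                          seed = derive_seed(seed, 3L, ri))
      ids <- next_id:(next_id + k - 1L)
      vert_assign[idx] <- ids[cl]
      sub_rows[[length(sub_rows) + 1L]] <- tibble(
        subregion_id = ids,
        region = regions[ri],
        hemisphere = h,
        n_vertices = tabulate(cl, k)
      )
      next_id <- next_id + k
    }
  }
  structure(
    list(
      vertex = tibble(vertex_id = template$vertex_id,
                      subregion_id = vert_assign),
      subregions = dplyr::bind_rows(sub_rows)
    ),
    class = "hemimorph_parcellation"
  )
}

# Seeded, deterministic k-means for one region; retries once with a fresh
# seed if Lloyd leaves an empty cluster.
region_kmeans <- function(xyz, k, seed) {
  if (k == 1L) return(rep(1L, nrow(xyz)))
  run <- function(s) {
    init <- with_seed(s, farthest_point_seeds(xyz, k))
    km <- tryCatch(
      suppressWarnings(stats::kmeans(xyz, centers = xyz[init, , drop = FALSE],
                                     iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(km) || any(tabulate(km$cluster, k) == 0L)) NULL else km$cluster
  }
  cl <- run(seed)
  if (is.null(cl)) cl <- run(derive_seed(seed, 99L))
  if (is.null(cl)) stop_input("k-means produced an empty subregion after re-seeding")
  cl
}

#' Write / read a parcellation
#'
#' Two TSV files: a vertex assignment (`vertex_id`, `subregion_id`) and a
#' subregion table (`subregion_id`, `region`, `hemisphere`, `n_vertices`).
#'
#' @param parcellation a `hemimorph_parcellation`.
#' @param vertex_path,subregion_path file paths.
#' @return the parcellation (reader) or paths invisibly (writer).
#' @export
write_parcellation <- function(parcellation, vertex_path, subregion_path) {
  readr::write_tsv(parcellation$vertex, vertex_path)
  readr::write_tsv(parcellation$subregions, subregion_path)
  invisible(c(vertex_path, subregion_path))
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(vertex_path, subregion_path) {
  structure(
    list(
      vertex = readr::read_tsv(vertex_path,
                               col_types = readr::cols(
                                 vertex_id = readr::col_integer(),
                                 subregion_id = readr::col_integer())),
      subregions = readr::read_tsv(subregion_path,
                                   col_types = readr::cols(
                                     subregion_id = readr::col_integer(),
                                     region = readr::col_character(),
                                     hemisphere = readr::col_character(),
                                     n_vertices = readr::col_integer()))
    ),
    class = "hemimorph_parcellation"
  )
}
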