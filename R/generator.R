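#' Configure the synthetic cohort generator
#'
#' The generator emulates surface-extraction output at the level this
#' pipeline consumes: two hemispheric unit-sphere point sets whose vertices
#' carry anatomical region labels and a cortical thickness value in mm, plus
#' a cohort manifest (gender, age, handedness, family). Thickness per subject
#' is `regional mean + smooth spatially autocorrelated field + i.i.d. vertex
#' noise`, with optional gender-by-hemisphere effects injected into chosen
#' regions so downstream asymmetry statistics have a known ground truth.
#'
#' @param n_female,n_male subjects per gender group (default 10 each, the
#'   package's reference validation cohort).
#' @param n_regions_per_hemisphere anatomical regions per hemisphere
#'   (default 39, i.e. 78 cortical regions in total).
#' @param vertices_per_region target mean vertex count of one *upsampled
#'   subregion* (default 150, matching the reported real-data subregion scale
#'   of about 149 +/- 22 vertices). The hemisphere surface is sized as
#'   `vertices_per_region * subregions_per_hemisphere`.
#' @param subregions_per_hemisphere number of network nodes per hemisphere
#'   the surface is dimensioned for (default 256).
#' @param thickness_mean_range range (mm) spanned by the regional mean
#'   thickness profile (default `c(1.5, 4.5)`).
#' @param within_region_sd total within-region thickness standard deviation
#'   in mm (default 0.35); split evenly (in variance) between the smooth
#'   spatial field and vertex-level noise.
#' @param spatial_autocorrelation_length dimensionless correlation length on
#'   the unit sphere (default 0.5); smaller values admit higher spherical
#'   harmonic orders, i.e. rougher fields.
#' @param effect_specs list of [effect_spec()] entries describing injected
#'   gender/hemisphere/region effects.
#' @param age_range inclusive age range in years (default `c(22, 36)`).
#' @param handedness_min minimum handedness score (must be >= 50 so the
#'   cohort filter passes by construction).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `hemimorph_generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(n_female = 2, n_male = 2, vertices_per_region = 40)
generator_config <- function(n_female = 10,
                             n_male = 10,
                             n_regions_per_hemisphere = 39,
                             vertices_per_region = 150,
                             subregions_per_hemisphere = 256,
                             thickness_mean_range = c(1.5, 4.5),
                             within_region_sd = 0.35,
                             spatial_autocorrelation_length = 0.5,
                             effect_specs = list(),
                             age_range = c(22, 36),
                             handedness_min = 50,
                             seed = 1L) {
  if (!is_count(n_female, 0) || !is_count(n_male, 0)) {
    stop_config("`n_female` and `n_male` must be non-negative integers")
  }
  if (!is_count(n_regions_per_hemisphere)) {
    stop_config("`n_regions_per_hemisphere` must be a positive integer")
  }
  if (!is_count(vertices_per_region) || !is_count(subregions_per_hemisphere)) {
    stop_config("vertex and subregion counts must be positive integers")
  }
  if (length(thickness_mean_range) != 2 || any(thickness_mean_range <= 0) ||
      diff(thickness_mean_range) <= 0) {
    stop_config("`thickness_mean_range` must be an increasing positive interval")
  }
  if (!is_number(within_region_sd) || within_region_sd <= 0) {
    stop_config("`within_region_sd` must be a positive number (mm)")
  }
  if (!is_number(spatial_autocorrelation_length) ||
      spatial_autocorrelation_length <= 0) {
    stop_config("`spatial_autocorrelation_length` must be positive")
  }
  if (length(age_range) != 2 || diff(age_range) < 0) {
    stop_config("`age_range` must be an interval")
  }
  if (!is_number(handedness_min) || handedness_min < 50) {
    stop_config("`handedness_min` must be >= 50")
  }
  if (!is_count(seed, 0)) stop_config("`seed` must be a non-negative integer")
  if (!is.list(effect_specs) ||
      !all(vapply(effect_specs, inherits, logical(1), "hemimorph_effect_spec"))) {
    stop_config("`effect_specs` must be a list of effect_spec() entries")
  }
  structure(
    list(
      n_female = as.integer(n_female),
      n_male = as.integer(n_male),
      n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
      vertices_per_region = as.integer(vertices_per_region),
      subregions_per_hemisphere = as.integer(subregions_per_hemisphere),
      thickness_mean_range = as.numeric(thickness_mean_range),
      within_region_sd = within_region_sd,
      spatial_autocorrelation_length = spatial_autocorrelation_length,
      effect_specs = effect_specs,
      age_range = as.numeric(age_range),
      handedness_min = handedness_min,
      seed = as.integer(seed)
    ),
    class = "hemimorph_generator_config"
  )
}

#' Describe one injected gender-by-hemisphere effect
#'
#' An effect shifts the mean and/or rescales the stochastic spread of the
#' thickness field in one (region, hemisphere) for subjects of one gender,
#' leaving every other vertex untouched.
#'
#' @param region anatomical region label (must exist in the surface template).
#' @param hemisphere `"L"` or `"R"`.
#' @param gender `"F"` or `"M"`.
#' @param mean_shift additive shift of the regional mean, mm.
#' @param sd_scale multiplicative scale of the stochastic component.
#' @return a `hemimorph_effect_spec` list.
#' @export
effect_spec <- function(region, hemisphere, gender, mean_shift = 0, sd_scale = 1) {
  if (!is.character(region) || length(region) != 1L) {
    stop_config("`region` must be a single region label")
  }
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  gender <- match.arg(gender, c("F", "M"))
  if (!is_number(mean_shift) || !is_number(sd_scale) || sd_scale <= 0) {
    stop_config("`mean_shift` must be finite and `sd_scale` positive")
  }
  structure(
    list(region = region, hemisphere = hemisphere, gender = gender,
         mean_shift = mean_shift, sd_scale = sd_scale),
    class = "hemimorph_effect_spec"
  )
}

# Minimum vertices an upsampled subregion may hold; the surface generator
# guarantees each anatomical region can host at least two such subregions.
MIN_SUBREGION_VERTICES <- 30L

#' Generate a labeled hemispheric surface template
#'
#' Draws vertices uniformly on the unit sphere, partitions them into
#' contiguous anatomical regions by k-means on the sphere coordinates
#' (nearest-seed cells with balanced sizes), and mirrors the left-hemisphere
#' layout through the sagittal plane to obtain homologous right-hemisphere
#' regions. The template carries no thickness; [generate_cohort()] fills it
#' per subject.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `vertex_id`, `hemisphere`, `x`, `y`, `z`,
#'   `region`.
#' @export
generate_surface <- function(config) {
  stopifnot(inherits(config, "hemimorph_generator_config"))
  n_regions <- config$n_regions_per_hemisphere
  n_hemi <- config$vertices_per_region * config$subregions_per_hemisphere
  min_region <- 2L * MIN_SUBREGION_VERTICES
  if (n_regions * min_region > n_hemi) {
    stop_config(sprintf(
      "vertex budget too small: %d regions x %d minimum vertices exceeds %d vertices per hemisphere",
      n_regions, min_region, n_hemi
    ))
  }
  labels <- region_labels(n_regions)
  with_seed(derive_seed(config$seed, 0L), {
    for (attempt in 1:20) {
      xyz <- matrix(rnorm(3L * n_hemi), ncol = 3L)
      xyz <- xyz / sqrt(rowSums(xyz^2))
      if (n_regions == 1L) {
        assign_idx <- rep(1L, n_hemi)
      } else {
        init <- farthest_point_seeds(xyz, n_regions)
        km <- suppressWarnings(
          stats::kmeans(xyz, centers = xyz[init, , drop = FALSE],
                        iter.max = 100L, algorithm = "Lloyd")
        )
        assign_idx <- km$cluster
      }
      sizes <- tabulate(assign_idx, n_regions)
      if (min(sizes) >= min_region) break
      if (attempt == 20L) {
        stop_config("could not partition the sphere into regions above the size floor")
      }
    }
    left <- tibble(
      vertex_id = seq_len(n_hemi),
      hemisphere = "L",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      region = labels[assign_idx]
    )
    right <- tibble(
      vertex_id = n_hemi + seq_len(n_hemi),
      hemisphere = "R",
      x = -xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      region = labels[assign_idx]
    )
    dplyr::bind_rows(left, right)
  })
}

# Farthest-point seeding: first seed from the RNG, then repeatedly the vertex
# farthest from the chosen set; ties resolved to the lowest vertex id (the
# first maximum).
farthest_point_seeds <- function(xyz, k) {
  n <- nrow(xyz)
  seeds <- integer(k)
  seeds[1] <- sample.int(n, 1L)
  mind <- colSums((t(xyz) - xyz[seeds[1], ])^2)
  if (k > 1) {
    for (j in 2:k) {
      seeds[j] <- which.max(mind)
      mind <- pmin(mind, colSums((t(xyz) - xyz[seeds[j], ])^2))
    }
  }
  seeds
}

# Regional mean-thickness profile: a fixed ladder, evenly spaced over the
# configured range in canonical label order and identical for homologous
# left/right regions, so the null cohort is exactly L/R exchangeable.
region_mean_profile <- function(config) {
  labels <- region_labels(config$n_regions_per_hemisphere)
  means <- if (length(labels) == 1L) {
    mean(config$thickness_mean_range)
  } else {
    seq(config$thickness_mean_range[1], config$thickness_mean_range[2],
        length.out = length(labels))
  }
  setNames(means, labels)
}

#' Real spherical-harmonic basis on given sphere points
#'
#' Basis of real spherical harmonics up to a maximum degree set by the
#' autocorrelation length (`l_max = clamp(round(2 / length), 1, 8)`). Used to
#' draw smooth random thickness fields.
#'
#' @param xyz matrix of unit-norm coordinates.
#' @param autocorr_length correlation length parameter.
#' @return numeric matrix, one column per harmonic.
#' @keywords internal
sh_basis <- function(xyz, autocorr_length) {
  l_max <- max(1L, min(8L, as.integer(round(2 / autocorr_length))))
  ct <- xyz[, 3]                      # cos(theta)
  phi <- atan2(xyz[, 2], xyz[, 1])
  cols <- list(rep(1 / sqrt(4 * pi), nrow(xyz)))
  for (l in seq_len(l_max)) {
    P <- pracma::legendre(l, ct)      # (l+1) x n, rows m = 0..l
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        cols[[length(cols) + 1L]] <- nrm * P[1, ]
      } else {
        cols[[length(cols) + 1L]] <- sqrt(2) * nrm * P[m + 1, ] * cos(m * phi)
        cols[[length(cols) + 1L]] <- sqrt(2) * nrm * P[m + 1, ] * sin(m * phi)
      }
    }
  }
  do.call(cbind, cols)
}

#' Generate a synthetic cohort of thickness-labeled vertex tables
#'
#' For each subject, thickness is the regional mean profile plus a smooth
#' spherical-harmonic random field plus i.i.d. vertex noise (field and noise
#' each carry half the configured within-region variance), floored at 0.1 mm.
#' Effects listed in `config$effect_specs` are applied only to vertices whose
#' (gender, hemisphere, region) matches. The manifest rows satisfy the
#' cohort-selection filter by construction.
#'
#' @param template surface from [generate_surface()].
#' @param config the [generator_config()] used for the template.
#' @return list with `subjects` (named list of vertex tables) and `manifest`
#'   (tibble: subject_id, gender, age, handedness, family_id).
#' @export
generate_cohort <- function(template, config) {
  manifest <- cohort_manifest(config)
  basis <- cohort_field_basis(template, config)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    generate_subject(template, config, manifest$gender[i], i, basis = basis)
  })
  names(subjects) <- manifest$subject_id
  list(subjects = subjects, manifest = manifest)
}

#' @rdname generate_cohort
#' @export
cohort_manifest <- function(config) {
  stopifnot(inherits(config, "hemimorph_generator_config"))
  n <- config$n_female + config$n_male
  with_seed(derive_seed(config$seed, 1L), {
    tibble(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      gender = rep(c("F", "M"), c(config$n_female, config$n_male)),
      age = sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE),
      handedness = sample(seq(config$handedness_min, 100), n, replace = TRUE),
      family_id = sprintf("fam-%03d", seq_len(n))
    )
  })
}

# Precompute the per-hemisphere harmonic basis for a template (shared across
# subjects; the expensive part of field evaluation).
cohort_field_basis <- function(template, config) {
  check_effect_regions(template, config)
  lapply(split(template[, c("x", "y", "z")], template$hemisphere), function(d) {
    sh_basis(as.matrix(d), config$spatial_autocorrelation_length)
  })
}

check_effect_regions <- function(template, config) {
  known <- unique(template$region)
  for (spec in config$effect_specs) {
    if (!spec$region %in% known) {
      stop_config(sprintf("effect spec names unknown region '%s'", spec$region))
    }
  }
  invisible(TRUE)
}

#' Generate one subject's thickness field
#'
#' Exposed separately so large simulation studies can stream subjects
#' without holding a whole cohort in memory. Subject `i` of a given config is
#' identical whether generated via [generate_cohort()] or directly.
#'
#' @param template surface template.
#' @param config generator config.
#' @param gender `"F"` or `"M"` for this subject.
#' @param subject_index 1-based index of the subject in the cohort manifest.
#' @param basis optional precomputed [cohort_field_basis()].
#' @return the template with a `thickness` column appended.
#' @export
generate_subject <- function(template, config, gender, subject_index,
                             basis = NULL) {
  if (is.null(basis)) basis <- cohort_field_basis(template, config)
  profile <- region_mean_profile(config)
  comp_sd <- config$within_region_sd / sqrt(2)
  with_seed(derive_seed(config$seed, 2L, subject_index), {
    stoch <- numeric(nrow(template))
    for (h in c("L", "R")) {
      idx <- which(template$hemisphere == h)
      B <- basis[[h]]
      field <- as.numeric(B %*% rnorm(ncol(B)))
      field <- field / sd(field) * comp_sd
      stoch[idx] <- field + rnorm(length(idx), 0, comp_sd)
    }
    base <- unname(profile[template$region])
    shift <- numeric(nrow(template))
    scale <- rep(1, nrow(template))
    for (spec in config$effect_specs) {
      if (spec$gender != gender) next
      m <- template$hemisphere == spec$hemisphere & template$region == spec$region
      shift[m] <- shift[m] + spec$mean_shift
      scale[m] <- scale[m] * spec$sd_scale
    }
    out <- template
    out$thickness <- pmax(0.1, base + shift + scale * stoch)
    out
  })
}
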