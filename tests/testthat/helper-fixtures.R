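# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# Reduced-scale generator config: 8 anatomical regions and 32 network nodes
# per hemisphere, 40-vertex subregions. Exercises every code path at a
# fraction of the default cost.
tiny_config <- function(seed = 101, ...) {
  generator_config(
    n_female = 3, n_male = 3,
    n_regions_per_hemisphere = 8,
    vertices_per_region = 40,
    subregions_per_hemisphere = 32,
    seed = seed,
    ...
  )
}

tiny_world <- function() {
  memo("tiny_world", function() {
    cfg <- tiny_config()
    template <- generate_surface(cfg)
    parcellation <- upsample_parcellation(template, 32, seed = 5)
    cohort <- generate_cohort(template, cfg)
    list(config = cfg, template = template, parcellation = parcellation,
         cohort = cohort)
  })
}

# Default-scale surface and 512-subregion parcellation (39 regions, ~150
# vertices per subregion); a few seconds to build, shared by every file
# that needs the full 256-node geometry.
default_world <- function() {
  memo("default_world", function() {
    cfg <- generator_config(seed = 11)
    template <- generate_surface(cfg)
    parcellation <- upsample_parcellation(template, 256, seed = 5)
    list(config = cfg, template = template, parcellation = parcellation,
         basis = hemimorph:::cohort_field_basis(template, cfg))
  })
}

# Seeded Erdos-Renyi-style random adjacency matrix.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  on <- ut[runif(length(ut)) < p]
  A[on] <- 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# Random discrete distribution on a shared mesh.
random_density <- function(k = 27, seed = 1) {
  set.seed(seed)
  m <- runif(k)
  m <- m / sum(m)
  attr(m, "grid") <- seq_len(k)
  m
}

ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (d in seq_len(k %/% 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}
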