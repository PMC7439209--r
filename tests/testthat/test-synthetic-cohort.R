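test_that("surface generation is deterministic and respects the region budget", {
  cfg <- tiny_config()
  t1 <- generate_surface(cfg)
  t2 <- generate_surface(cfg)
  expect_identical(t1, t2)
  expect_equal(length(unique(t1$region)), 8)
  expect_setequal(unique(t1$hemisphere), c("L", "R"))
  # unit-norm coordinates, disjoint hemispheres, region floor
  expect_lt(max(abs(sqrt(t1$x^2 + t1$y^2 + t1$z^2) - 1)), 1e-6)
  expect_equal(anyDuplicated(t1$vertex_id), 0)
  sizes <- table(t1$region, t1$hemisphere)
  expect_true(all(sizes >= 60))
})

test_that("default-scale surface carries the 78-region cortical scheme", {
  w <- default_world()
  expect_equal(length(unique(paste(w$template$region, w$template$hemisphere))),
               78)
  expect_true("TPOmid" %in% w$template$region)
})

test_that("degenerate single-region partition labels every vertex alike", {
  cfg <- generator_config(n_regions_per_hemisphere = 1, vertices_per_region = 25,
                          subregions_per_hemisphere = 4, seed = 3)
  tpl <- generate_surface(cfg)
  expect_equal(nrow(tpl), 200)
  expect_equal(unique(tpl$region), "PreCG")
})

test_that("vertex budget too small for the region floor is a config error", {
  cfg <- generator_config(n_regions_per_hemisphere = 10, vertices_per_region = 10,
                          subregions_per_hemisphere = 20, seed = 3)
  expect_error(generate_surface(cfg), class = "hemimorph_config_error")
})

test_that("cohort manifest matches configured group sizes and study filters", {
  m <- cohort_manifest(generator_config(n_female = 150, n_male = 135, seed = 2))
  expect_equal(nrow(m), 285)
  expect_equal(sum(m$gender == "F"), 150)
  expect_true(all(m$handedness >= 50))
  expect_true(all(m$age >= 22 & m$age <= 36))
  expect_equal(anyDuplicated(m$subject_id), 0)
  expect_equal(anyDuplicated(m$family_id), 0)
})

test_that("cohort generation is deterministic and positive-thickness", {
  w <- tiny_world()
  coh2 <- generate_cohort(w$template, w$config)
  expect_identical(w$cohort$subjects[["sub-002"]], coh2$subjects[["sub-002"]])
  s <- w$cohort$subjects[[1]]
  expect_true(all(s$thickness > 0))
  # streaming single-subject generation agrees with the cohort path
  s4 <- generate_subject(w$template, w$config,
                         w$cohort$manifest$gender[4], 4)
  expect_identical(s4, w$cohort$subjects[[4]])
})

test_that("effect specs referencing unknown regions are rejected", {
  cfg <- tiny_config(effect_specs = list(effect_spec("NOPE", "L", "F", 0.5)))
  tpl <- generate_surface(tiny_config())
  expect_error(generate_cohort(tpl, cfg), class = "hemimorph_config_error")
})

test_that("an injected mean shift moves the targeted regional mean by that amount", {
  shift <- 0.5
  cfg <- tiny_config(
    seed = 55,
    effect_specs = list(effect_spec("ORBsup", "L", "F", mean_shift = shift))
  )
  tpl <- generate_surface(cfg)
  basis <- hemimorph:::cohort_field_basis(tpl, cfg)
  # Monte-Carlo over 20 female subjects; each contributes ~2k vertices per side
  diffs <- vapply(1:20, function(i) {
    s <- generate_subject(tpl, cfg, "F", i, basis = basis)
    mean(s$thickness[s$region == "ORBsup" & s$hemisphere == "L"]) -
      mean(s$thickness[s$region == "ORBsup" & s$hemisphere == "R"])
  }, numeric(1))
  expect_equal(mean(diffs), shift, tolerance = 0.05)
  # males untouched
  diffs_m <- vapply(1:5, function(i) {
    s <- generate_subject(tpl, cfg, "M", i, basis = basis)
    mean(s$thickness[s$region == "ORBsup" & s$hemisphere == "L"]) -
      mean(s$thickness[s$region == "ORBsup" & s$hemisphere == "R"])
  }, numeric(1))
  expect_lt(abs(mean(diffs_m)), 0.1)
})

test_that("null cohort asymmetry is sign-balanced over many subjects", {
  w <- tiny_world()
  basis <- hemimorph:::cohort_field_basis(w$template, w$config)
  ai <- vapply(1:200, function(i) {
    s <- generate_subject(w$template, w$config, "F", i, basis = basis)
    d <- subject_degree_asymmetry(s, w$parcellation)
    d$AI[d$region == "MFG"]
  }, numeric(1))
  # sign balance: binomial 99.9% band around 0.5 for n = 200
  pos <- sum(ai > 0)
  band <- qbinom(c(0.0005, 0.9995), 200, 0.5)
  expect_gte(pos, band[1])
  expect_lte(pos, band[2])
})

test_that("larger injected shifts produce larger expected degree asymmetry", {
  # target the region at the thick end of the regional profile and shift it
  # toward the cortical bulk; three shift magnitudes, 15 subjects each
  shifts <- c(-0.2, -0.5, -0.8)
  mean_ai <- vapply(shifts, function(sh) {
    cfg <- tiny_config(
      seed = 77,
      effect_specs = list(effect_spec("ORBinf", "L", "F", mean_shift = sh))
    )
    tpl <- generate_surface(tiny_config(seed = 77))
    parc <- upsample_parcellation(tpl, 32, seed = 5)
    basis <- hemimorph:::cohort_field_basis(tpl, cfg)
    mean(vapply(1:15, function(i) {
      s <- generate_subject(tpl, cfg, "F", i, basis = basis)
      d <- subject_degree_asymmetry(s, parc)
      d$AI[d$region == "ORBinf"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(abs(mean_ai)) > 0))
})
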