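make_rm_data <- function(n = 20, seed = 1, gender_shift = 0, hemi_shift = 0,
                         inter_shift = 0) {
  set.seed(seed)
  gender <- rep(c("F", "M"), length.out = n)
  base <- rnorm(n, 3, 0.5)
  tibble::tibble(
    subject_id = sprintf("s%03d", 1:n),
    gender = gender,
    age = sample(22:36, n, TRUE),
    left = base + hemi_shift / 2 + ifelse(gender == "F", gender_shift / 2, 0) +
      ifelse(gender == "F", inter_shift / 2, -inter_shift / 2) + rnorm(n, 0, 0.3),
    right = base - hemi_shift / 2 + ifelse(gender == "F", gender_shift / 2, 0) -
      ifelse(gender == "F", inter_shift / 2, -inter_shift / 2) + rnorm(n, 0, 0.3)
  )
}

test_that("repeated-measures ANOVA handles degenerate designs exactly", {
  d <- make_rm_data(16, seed = 3)
  d$right <- d$left   # no hemisphere difference at all
  res <- rm_anova(d)
  expect_equal(res$F[res$effect == "hemisphere"], 0)
  expect_equal(res$F[res$effect == "gender:hemisphere"], 0)
  expect_equal(res$p[res$effect == "hemisphere"], 1)

  # identical data in both genders: gender indistinguishable
  d2 <- make_rm_data(10, seed = 4)
  dup <- d2
  dup$gender <- "M"
  d2$gender <- "F"
  dup$subject_id <- paste0(dup$subject_id, "m")
  both <- rbind(d2, dup)
  both$age <- rep(both$age[1:10], 2)
  res2 <- rm_anova(both)
  expect_equal(res2$F[res2$effect == "gender"], 0, tolerance = 1e-10)
})

test_that("the two-model decomposition matches the multivariate GLM oracle", {
  skip_if_not_installed("car")
  for (s in 1:6) {
    d <- make_rm_data(n = 17 + s, seed = 40 + s, gender_shift = 0.2,
                      hemi_shift = 0.15, inter_shift = 0.1)
    mine <- rm_anova(d)
    g <- factor(d$gender)
    contrasts(g) <- contr.sum(2)
    mlm <- lm(cbind(left, right) ~ g + I(age - mean(age)), data = d)
    av <- summary(car::Anova(mlm, idata = data.frame(hemi = factor(c("L", "R"))),
                             idesign = ~hemi, type = 3),
                  multivariate = FALSE)$univariate.tests
    expect_equal(mine$F[mine$effect == "gender"], av["g", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "hemisphere"], av["hemi", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "gender:hemisphere"],
                 av["g:hemi", "F value"], tolerance = 1e-8)
    expect_equal(mine$df2[1], unname(av["g", "den Df"]))
  }
})

test_that("one-sample t on asymmetry indexes matches the closed form", {
  res <- one_sample_t(c(2, 4, 6))
  expect_equal(res$t, 4 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(one_sample_t(c(-1, 1))$t, 0)
  a <- one_sample_t(c(1, 3, 4, 7))
  b <- one_sample_t(-c(1, 3, 4, 7))
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  expect_error(one_sample_t(c(2, 2, 2)), class = "hemimorph_input_error")
})

test_that("two-sample t uses the pooled variance with group-swap antisymmetry", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(two_sample_t(c(1, 2), c(1, 2))$t, 0)
  sw <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -res$t)
  # degenerate equal constant groups resolve to t = 0 by convention
  degen <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(degen$t, 0)
  expect_equal(degen$p, 1)
  # Welch flag reaches the unequal-variance test
  wl <- two_sample_t(c(1, 2, 3, 7), c(2, 2.1, 2.2), welch = TRUE)
  expect_lt(wl$df, 5)
})

test_that("Benjamini-Hochberg step-up rejection matches its thresholds", {
  res <- fdr_bh(c(0.002, 0.01, 0.03, 0.04), q = 0.05)
  expect_true(all(res$rejected))
  expect_true(all(res$p_adjusted >= res$p))
  expect_false(any(fdr_bh(rep(1, 6))$rejected))
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  # step-up thresholds k * q / m: only the smallest p clears its rank here
  res2 <- fdr_bh(c(0.04, 0.2, 0.001), q = 0.05)
  expect_equal(res2$rejected, c(FALSE, FALSE, TRUE))
  expect_equal(res2$p_adjusted, c(0.06, 0.2, 0.003))
  expect_error(fdr_bh(c(0.5, 0)), class = "hemimorph_input_error")
})

test_that("the AI battery tests per metric with FDR over the region family", {
  set.seed(91)
  n <- 24
  manifest <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    gender = rep(c("F", "M"), each = n / 2),
    age = sample(22:36, n, TRUE),
    handedness = 80, family_id = sprintf("f%02d", 1:n)
  )
  regions <- paste0("R", 1:6)
  ai <- tidyr::expand_grid(subject_id = manifest$subject_id,
                           metric = c("degree", "E_nodal"),
                           region = regions)
  ai$scope <- "region"
  ai$AI <- rnorm(nrow(ai), 0, 5)
  # inject a strong female-only leftward effect in R3/degree
  sel <- ai$region == "R3" & ai$metric == "degree" &
    ai$subject_id %in% manifest$subject_id[manifest$gender == "F"]
  ai$AI[sel] <- ai$AI[sel] + 25
  glob <- tidyr::expand_grid(subject_id = manifest$subject_id,
                             metric = c("Lp", "E_global"))
  glob$scope <- "global"; glob$region <- NA_character_
  glob$AI <- rnorm(nrow(glob), 0, 5)
  res <- ai_test_battery(rbind(glob, ai[, names(glob)]), manifest)

  expect_setequal(unique(res$global$metric), c("Lp", "E_global"))
  expect_setequal(unique(res$local$test), c("one_sample", "two_sample"))
  hit <- res$local[res$local$region == "R3" & res$local$metric == "degree" &
                     res$local$test == "two_sample", ]
  expect_true(hit$significant)
  expect_gt(hit$t, 0)
  # FDR applied within (metric, test, group) families of 6 regions
  fam <- res$local[res$local$metric == "E_nodal" &
                     res$local$test == "one_sample" & res$local$group == "F", ]
  expect_equal(nrow(fam), 6)
  expect_equal(fam$significant, fdr_bh(fam$p)$rejected)
})
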