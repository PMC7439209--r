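#' Two-way repeated-measures ANOVA with an age covariate
#'
#' Hemisphere (left/right) is the within-subject factor, gender the
#' between-subject factor, and age a linear, mean-centered covariate. With a
#' two-level within factor the design decomposes exactly into two
#' between-subject linear models:
#' the subject L/R *mean* regressed on gender + age yields the gender main
#' effect, and the L - R *difference* regressed on gender + age yields the
#' hemisphere main effect (intercept term, with sum-coded gender) and the
#' gender-by-hemisphere interaction (gender term). F statistics are partial
#' (Type III) F tests with 1 and n - 3 degrees of freedom; terms with zero
#' partial sum of squares are reported as F = 0.
#'
#' @param data tibble with columns `subject_id`, `gender` (`"F"`/`"M"`),
#'   `age`, `left`, `right` (one row per subject).
#' @return tibble with columns `effect` (`gender`, `hemisphere`,
#'   `gender:hemisphere`), `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(data) {
  need <- c("subject_id", "gender", "age", "left", "right")
  if (!all(need %in% names(data))) {
    stop_input(paste("rm_anova needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(data$subject_id)) {
    stop_input("one row per subject required (both hemispheres on one row)")
  }
  n <- nrow(data)
  if (length(unique(data$gender)) < 2 || min(table(data$gender)) < 2) {
    stop_input("need at least 2 subjects in each gender group")
  }
  if (n < 4 || length(unique(data$age)) < 2) {
    stop_input("singular design: need n >= 4 and non-constant age")
  }
  g <- ifelse(data$gender == "F", 1, -1)          # sum coding
  age_c <- data$age - mean(data$age)
  m <- (data$left + data$right) / 2
  d <- data$left - data$right
  df2 <- n - 3L

  partial_f <- function(y, full, reduced) {
    rss <- function(X) {
      fit <- stats::lm.fit(X, y)
      sum(fit$residuals^2)
    }
    rss_full <- rss(full)
    ss <- max(rss(reduced) - rss_full, 0)
    if (ss <= 0) return(0)
    if (rss_full <= 0) return(Inf)
    (ss / 1) / (rss_full / df2)
  }

  one <- rep(1, n)
  X_full <- cbind(one, g, age_c)
  F_gender <- partial_f(m, X_full, cbind(one, age_c))
  F_hemi <- partial_f(d, X_full, cbind(g, age_c))
  F_inter <- partial_f(d, X_full, cbind(one, age_c))
  Fs <- c(F_gender, F_hemi, F_inter)
  tibble(
    effect = c("gender", "hemisphere", "gender:hemisphere"),
    F = Fs, df1 = 1L, df2 = df2,
    p = ifelse(is.finite(Fs), pf(Fs, 1, df2, lower.tail = FALSE), 0)
  )
}

#' One-sample t-test on asymmetry indexes
#'
#' Tests whether the mean asymmetry index differs from 0 within one group;
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom, two-sided.
#'
#' @param ai numeric vector of per-subject AI values.
#' @return tibble with `t`, `df`, `p`, `mean_ai`, `n`.
#' @export
one_sample_t <- function(ai) {
  ai <- ai[!is.na(ai)]
  if (length(ai) < 2) stop_input("need at least 2 values")
  if (sd(ai) == 0) stop_input("zero variance: t statistic undefined")
  ht <- stats::t.test(ai, mu = 0)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_ai = mean(ai), n = length(ai))
}

#' Two-sample t-test on asymmetry indexes between groups
#'
#' Pooled-variance Student t by default (`welch = TRUE` for the
#' Welch-Satterthwaite variant), two-sided. The degenerate case of two
#' zero-variance groups with equal means is reported as t = 0, p = 1.
#'
#' @param ai_a,ai_b AI values of the two groups (first minus second).
#' @param welch use Welch's unequal-variance test.
#' @return tibble with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(ai_a, ai_b, welch = FALSE) {
  ai_a <- ai_a[!is.na(ai_a)]
  ai_b <- ai_b[!is.na(ai_b)]
  if (length(ai_a) < 2 || length(ai_b) < 2) {
    stop_input("need at least 2 values per group")
  }
  if (sd(ai_a) == 0 && sd(ai_b) == 0) {
    if (mean(ai_a) == mean(ai_b)) {
      return(tibble(t = 0, df = length(ai_a) + length(ai_b) - 2L, p = 1,
                    mean_a = mean(ai_a), mean_b = mean(ai_b)))
    }
    return(tibble(t = sign(mean(ai_a) - mean(ai_b)) * Inf,
                  df = length(ai_a) + length(ai_b) - 2L, p = 0,
                  mean_a = mean(ai_a), mean_b = mean(ai_b)))
  }
  ht <- stats::t.test(ai_a, ai_b, var.equal = !welch)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, mean_a = mean(ai_a), mean_b = mean(ai_b))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control at level `q`: adjusted p values are
#' `min over k >= rank of (m * p_(k) / k)` capped at 1, and a test is
#' rejected exactly when its adjusted p value is at most `q`.
#'
#' @param p vector of raw p values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return tibble with `p`, `p_adjusted`, `rejected`, in input order.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) {
    return(tibble(p = numeric(), p_adjusted = numeric(),
                  rejected = logical()))
  }
  if (any(is.na(p) | p <= 0 | p > 1)) stop_input("p values must lie in (0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, p_adjusted = adj, rejected = adj <= q)
}

#' Run the full asymmetry test battery on a cohort AI table
#'
#' For every global metric: a one-sample t-test of the AI within each
#' gender and a pooled two-sample t-test between genders, assessed at
#' uncorrected p < `alpha`. For every local metric: the same tests per
#' homologous region pair, with Benjamini-Hochberg FDR across the region
#' family, applied separately per metric, per test.
#'
#' @param ai_table per-subject AI table with columns `subject_id`, `scope`,
#'   `metric`, `region`, `AI` (rows from [subject_asymmetry()], one set per
#'   subject).
#' @param manifest cohort manifest supplying `gender` per subject.
#' @param alpha significance level for global (uncorrected) tests.
#' @param q FDR level for region families.
#' @return list of tibbles `global` and `local`.
#' @export
ai_test_battery <- function(ai_table, manifest, alpha = 0.05, q = 0.05) {
  ai_table$gender <- manifest$gender[match(ai_table$subject_id,
                                           manifest$subject_id)]
  if (anyNA(ai_table$gender)) stop_input("AI table has subjects missing from manifest")

  run_tests <- function(df) {
    f <- df$AI[df$gender == "F"]
    m <- df$AI[df$gender == "M"]
    dplyr::bind_rows(
      dplyr::mutate(one_sample_t(f), test = "one_sample", group = "F"),
      dplyr::mutate(one_sample_t(m), test = "one_sample", group = "M"),
      dplyr::mutate(
        dplyr::rename(two_sample_t(f, m), mean_ai = "mean_a"),
        test = "two_sample", group = "F-M", n = length(f) + length(m)
      )
    )
  }

  glb <- ai_table[ai_table$scope == "global", ]
  global_res <- dplyr::bind_rows(lapply(split(glb, glb$metric), function(df) {
    res <- run_tests(df)
    res$metric <- df$metric[1]
    res
  }))
  global_res$significant <- global_res$p < alpha

  loc <- ai_table[ai_table$scope == "region", ]
  local_res <- NULL
  if (nrow(loc)) {
    per_region <- dplyr::bind_rows(lapply(
      split(loc, list(loc$metric, loc$region), drop = TRUE),
      function(df) {
        res <- run_tests(df)
        res$metric <- df$metric[1]
        res$region <- df$region[1]
        res
      }
    ))
    # FDR family = the homologous region pairs, per metric and per test/group
    local_res <- dplyr::bind_rows(lapply(
      split(per_region,
            list(per_region$metric, per_region$test, per_region$group),
            drop = TRUE),
      function(df) {
        fdr <- fdr_bh(df$p, q = q)
        df$p_fdr <- fdr$p_adjusted
        df$significant <- fdr$rejected
        df
      }
    ))
  }
  list(global = global_res, local = local_res)
}

#' Repeated-measures ANOVA over a cohort's integrated metrics
#'
#' Applies [rm_anova()] to every global metric and every
#' (region, local metric) cell of a cohort's integrated metric table, with
#' FDR correction across the region family for local effects.
#'
#' @param integrated_table tibble with columns `subject_id`, `scope`
#'   (`global`/`region`), `metric`, `region`, `hemisphere`, `value`.
#' @param manifest cohort manifest with `gender` and `age`.
#' @param q FDR level for region families.
#' @return list of tibbles `global` and `local` of per-effect F tests.
#' @export
anova_battery <- function(integrated_table, manifest, q = 0.05) {
  wide <- tidyr::pivot_wider(integrated_table, names_from = "hemisphere",
                             values_from = "value")
  wide$gender <- manifest$gender[match(wide$subject_id, manifest$subject_id)]
  wide$age <- manifest$age[match(wide$subject_id, manifest$subject_id)]
  wide$left <- wide$L
  wide$right <- wide$R

  glb <- wide[wide$scope == "global", ]
  global_res <- dplyr::bind_rows(lapply(split(glb, glb$metric), function(df) {
    res <- rm_anova(df)
    res$metric <- df$metric[1]
    res
  }))

  loc <- wide[wide$scope == "region", ]
  local_res <- NULL
  if (nrow(loc)) {
    local_res <- dplyr::bind_rows(lapply(
      split(loc, list(loc$metric, loc$region), drop = TRUE),
      function(df) {
        res <- rm_anova(df)
        res$metric <- df$metric[1]
        res$region <- df$region[1]
        res
      }
    ))
    local_res <- dplyr::bind_rows(lapply(
      split(local_res, list(local_res$metric, local_res$effect), drop = TRUE),
      function(df) {
        fdr <- fdr_bh(df$p, q = q)
        df$p_fdr <- fdr$p_adjusted
        df$significant <- fdr$rejected
        df
      }
    ))
  }
  list(global = global_res, local = local_res)
}
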