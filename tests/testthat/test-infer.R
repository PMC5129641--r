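test_that("combined-SE z comparison reproduces the reported interaction", {
  est <- hydroxyzine_trial_estimates()
  pick <- function(o, e) {
    r <- est[est$outcome == o & est$effect == e, ]
    effect_estimate(e, o, r$estimate, ci_low = r$ci_low, ci_high = r$ci_high)
  }
  cmp <- compare_effects(pick("drowsiness", "placebo_1"),
                         pick("drowsiness", "placebo_2"))
  expect_equal(cmp$difference, 35.1)
  # SEs recovered from the printed CIs combine to about the printed
  # interaction CI half-width
  expect_equal(cmp$combined_se, sqrt(12.81^2 + 8.11^2), tolerance = 1e-3)
  expect_lt(cmp$p, 0.05)
})

test_that("comparing an estimate with itself is null", {
  a <- effect_estimate("placebo_1", "drowsiness", 40, se = 5)
  cmp <- compare_effects(a, a)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
})

test_that("combined SE follows the root-sum-of-squares formula", {
  withr::with_seed(7, {
    for (i in 1:10) {
      se_a <- runif(1, 0.1, 20)
      se_b <- runif(1, 0.1, 20)
      a <- effect_estimate("placebo_1", "x", rnorm(1), se = se_a)
      b <- effect_estimate("placebo_2", "x", rnorm(1), se = se_b)
      cmp <- compare_effects(a, b)
      expect_equal(cmp$combined_se, sqrt(se_a^2 + se_b^2))
      expect_gte(cmp$combined_se, max(se_a, se_b))
      expect_equal(cmp$difference, a$estimate - b$estimate)
    }
  })
})

test_that("degenerate comparisons are flagged", {
  a <- effect_estimate("placebo_1", "x", 10, se = 0)
  b <- effect_estimate("placebo_2", "x", 5, se = 0)
  expect_warning(cmp <- compare_effects(a, b), "infinite")
  expect_identical(cmp$z, Inf)
  c1 <- effect_estimate("placebo_1", "x", 1, se = 1)
  c2 <- effect_estimate("placebo_2", "y", 1, se = 1)
  expect_error(compare_effects(c1, c2), "same outcome")
})

test_that("decomposition metrics follow the interaction-model arithmetic", {
  est <- hydroxyzine_trial_estimates()
  est$z <- est$estimate / est$se
  est$p <- 2 * pnorm(-abs(est$z))
  dec <- decompose_effects(est)

  m <- dec$metrics
  d <- m[m$outcome == "drowsiness", ]
  expect_equal(d$interaction, 75.9 - 40.8)
  expect_equal(d$effect_sum, 58.3 + 40.8)
  expect_equal(d$additivity_gap, 139.7 - (58.3 + 40.8))
  expect_equal(d$overestimation_pct, 100 * (69.2 - 58.3) / 58.3)
  expect_equal(d$interaction_share_pct, 100 * (75.9 - 40.8) / 139.7)

  # itchiness: no total reported -> derived metrics are NA, not fabricated
  i <- m[m$outcome == "itchiness", ]
  expect_true(is.na(i$additivity_gap))
  expect_true(is.na(i$interaction_share_pct))

  # shared-cell comparisons carry the dependence caveat
  gaps <- dec$comparisons[dec$comparisons$comparison == "additivity_gap", ]
  expect_true(all(!gaps$independent))
  expect_output(print(dec), "interaction")
})

test_that("null interaction yields null derived metrics", {
  eff <- dplyr::bind_rows(
    effect_estimate("placebo_1", "x", 20, se = 2),
    effect_estimate("placebo_2", "x", 20, se = 2),
    effect_estimate("model_drug", "x", 30, se = 2),
    effect_estimate("conventional_drug", "x", 30, se = 2),
    effect_estimate("total", "x", 50, se = 2)
  )
  m <- decompose_effects(eff)$metrics
  expect_equal(m$interaction, 0)
  expect_equal(m$overestimation_pct, 0)
  expect_equal(m$interaction_share_pct, 0)
})

test_that("exact signed-rank p matches full sign-pattern enumeration", {
  d6 <- c(3.1, -0.7, 5.4, 2.2, -1.9, 4.3)
  # records with one group-2 subject pair per difference
  recs <- tibble::tibble(
    subject = rep(1:6, each = 2),
    group = 2L,
    period = rep(1:2, 6),
    received = "P",
    told = rep(c("H", "P"), 6),
    outcome = "drowsiness",
    baseline_mm = 5,
    auc_mm_hr = as.vector(rbind(100 + d6, 100)),
    binary_count = 0L
  )
  np <- nonparametric_effect(recs, "placebo_2", "drowsiness")
  expect_equal(np$test, "signed-rank")
  expect_equal(np$n, 6)
  expect_equal(np$p, signed_rank_enumeration_p(d6))
})

test_that("identical period pairs give signed-rank p = 1", {
  recs <- tibble::tibble(
    subject = rep(1:5, each = 2),
    group = 2L, period = rep(1:2, 5), received = "P",
    told = rep(c("H", "P"), 5), outcome = "drowsiness",
    baseline_mm = 5, auc_mm_hr = 42, binary_count = 0L
  )
  expect_warning(np <- nonparametric_effect(recs, "placebo_2", "drowsiness"),
                 "zero")
  expect_equal(np$p, 1)
})

test_that("non-parametric tests detect the simulated placebo effects", {
  recs <- reduce_trial(
    simulate_trial(generative_params(), n_per_group = 80, seed = 17)
  )
  for (o in c("drowsiness", "mouth_dryness", "nausea")) {
    expect_lt(nonparametric_effect(recs, "placebo_1", o)$p, 0.05)
  }
  # between-scope rank-sum: drug effect on drowsiness
  md <- nonparametric_effect(recs, "model_drug", "drowsiness")
  expect_equal(md$test, "rank-sum")
  expect_lt(md$p, 0.05)
})

test_that("placebo-effect rank correlations behave at the extremes", {
  # perfectly shared subject effect, no noise -> rho = 1
  s <- c(5.3, 1.2, 9.8, 3.3, 7.1)
  recs <- tidyr::expand_grid(
    subject = 1:5, period = 1:2,
    outcome = c("drowsiness", "mouth_dryness")
  )
  recs$group <- 1L
  recs$received <- "H"
  recs$told <- ifelse(recs$period == 1, "H", "P")
  recs$baseline_mm <- 5
  recs$auc_mm_hr <- 100 + ifelse(recs$told == "H", s[recs$subject], 0)
  recs$binary_count <- 0L
  ct <- placebo_correlations(recs)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$effect, "placebo_1")
  expect_equal(ct$rho, 1)

  # direct rank oracle on a 5-subject toy with distinct effects per outcome
  s2 <- c(2.5, 8.1, 0.3, 6.6, 4.9)
  recs2 <- recs
  recs2$auc_mm_hr <- 100 + ifelse(
    recs2$told == "H",
    ifelse(recs2$outcome == "drowsiness", s[recs2$subject], s2[recs2$subject]),
    0
  )
  ct2 <- placebo_correlations(recs2)
  expect_equal(ct2$rho, stats::cor(rank(s), rank(s2)))
})

test_that("independent noise gives near-zero placebo correlations", {
  p <- null_params(sigma_resid = 10)
  recs <- reduce_trial(simulate_trial(p, n_per_group = 200, seed = 23))
  ct <- placebo_correlations(recs)
  expect_true(all(abs(ct$rho) < 0.2))
})
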