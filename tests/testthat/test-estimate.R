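test_that("ANCOVA matches the normal-equations oracle on noisy data", {
  recs <- small_noisy_records(n_per_group = 8, seed = 13)
  for (o in c("drowsiness", "nausea")) {
    oracle <- ancova_oracle(recs, o, "between")
    fit_b <- fit_ancova(recs, o, "between")
    for (nm in c("model_drug", "total", "drug_plus_interaction")) {
      est <- estimate_effect(fit_b, nm)
      expect_equal(est$estimate, oracle[[nm]]$estimate, tolerance = 1e-10)
      expect_equal(est$se, oracle[[nm]]$se, tolerance = 1e-10)
    }

    oracle_w <- ancova_oracle(recs, o, "within")
    fit_w <- fit_ancova(recs, o, "within")
    expect_equal(fit_w$df, oracle_w$df)
    for (nm in c("placebo_1", "placebo_2", "conventional_drug")) {
      est <- estimate_effect(fit_w, nm)
      expect_equal(est$estimate, oracle_w[[nm]]$estimate, tolerance = 1e-10)
      expect_equal(est$se, oracle_w[[nm]]$se, tolerance = 1e-10)
    }
  }
})

test_that("a noiseless simulated trial reproduces the calibrated effects", {
  p <- zero_noise_params()
  recs <- reduce_trial(simulate_trial(p, n_per_group = 12, seed = 2))
  eff <- suppressWarnings(estimate_all(recs))
  a_p <- profile_auc(p$profile_placebo)

  expected <- function(o, nm) {
    e <- p$effects[p$effects$outcome == o, ]
    switch(nm,
      placebo_1 = e$placebo_auc + e$interaction_auc,
      placebo_2 = e$placebo_auc,
      conventional_drug = e$drug_auc + p$lambda * e$interaction_auc,
      model_drug = e$drug_auc,
      total = e$drug_auc + e$placebo_auc + e$interaction_auc,
      drug_plus_interaction = e$drug_auc + e$interaction_auc
    )
  }
  for (o in vas_outcomes()) {
    for (nm in unique(eff$effect)) {
      got <- eff$estimate[eff$outcome == o & eff$effect == nm]
      expect_equal(got, expected(o, nm), tolerance = 1e-9,
                   label = paste(o, nm))
    }
  }

  # contrast-consistency identities at zero noise
  e_d <- eff[eff$outcome == "drowsiness", ]
  get <- function(nm) e_d$estimate[e_d$effect == nm]
  expect_equal(get("total"), get("placebo_1") + get("model_drug"),
               tolerance = 1e-9)
  expect_equal(get("total"), get("placebo_2") + get("drug_plus_interaction"),
               tolerance = 1e-9)
  expect_equal(get("conventional_drug") - get("model_drug"),
               p$lambda * (get("placebo_1") - get("placebo_2")),
               tolerance = 1e-9)
})

test_that("effect estimates are invariant to a constant baseline shift", {
  recs <- small_noisy_records(n_per_group = 10, seed = 5)
  shifted <- recs
  shifted$baseline_mm <- shifted$baseline_mm + 13
  shifted$auc_mm_hr <- shifted$auc_mm_hr + 7 * 13
  e1 <- estimate_all(recs, outcomes = "drowsiness")
  e2 <- estimate_all(shifted, outcomes = "drowsiness")
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
  expect_equal(e1$se, e2$se, tolerance = 1e-8)
})

test_that("absorbing subject effects shrinks within-contrast SEs", {
  recs <- reduce_trial(
    simulate_trial(generative_params(), n_per_group = 40, seed = 6)
  )
  fit_w <- fit_ancova(recs, "drowsiness", "within")
  fit_b <- fit_ancova(recs, "drowsiness", "between")
  se_within <- estimate_effect(fit_w, "placebo_1")$se
  # the same H/H - H/P contrast from the between fit, which leaves subject
  # variance in the residual
  cf <- fit_b$coef
  cvec <- stats::setNames(numeric(length(cf)), names(cf))
  cvec["conditionH/H"] <- 1
  cvec["conditionH/P"] <- -1
  se_between <- sqrt(drop(t(cvec) %*% fit_b$vcov %*% cvec))
  expect_lte(se_within, se_between)
})

test_that("the period coefficient recovers the generating period effect", {
  p <- generative_params()
  recs <- reduce_trial(simulate_trial(p, n_per_group = 160, seed = 31))
  fit_w <- fit_ancova(recs, "drowsiness", "within")
  # true adjusted period effect on the AUC scale is 25.3 mm*hr
  expect_lt(abs(fit_w$coef[["period2"]] - 25.3), 10)
})

test_that("scope and cell preconditions are enforced", {
  recs <- small_noisy_records(n_per_group = 6, seed = 3)
  fit_b <- fit_ancova(recs, "drowsiness", "between")
  expect_error(estimate_effect(fit_b, "placebo_1"), "within-scope")
  fit_w <- fit_ancova(recs, "drowsiness", "within")
  expect_error(estimate_effect(fit_w, "total"), "between-scope")
  expect_error(estimate_effect(fit_w, "banana"), "Unknown effect")
  # no repeated subjects -> within fit impossible
  expect_error(fit_ancova(recs[recs$period == 1, ], "drowsiness", "within"),
               "repeated subjects")
  expect_error(fit_ancova(recs, "vertigo", "between"), "No records")
})

test_that("estimate_all is deterministic and reports gaps explicitly", {
  recs <- small_noisy_records(n_per_group = 6, seed = 8)
  e1 <- estimate_all(recs)
  expect_equal(nrow(e1), 4 * 6)
  expect_identical(e1, estimate_all(recs))

  # dropping group 3 leaves the conventional contrast unestimable
  no_g3 <- recs[recs$group != 3, ]
  expect_warning(e2 <- estimate_all(no_g3, outcomes = "drowsiness"),
                 "conventional_drug")
  expect_true(is.na(e2$estimate[e2$effect == "conventional_drug"]))
  expect_false(anyNA(e2$estimate[e2$effect == "placebo_1"]))
})
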