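test_that("trapezoidal AUC handles canonical cases", {
  grid <- vas_time_grid()
  expect_equal(compute_auc(grid, rep(100, 11)), 700)
  expect_equal(compute_auc(grid, rep(0, 11)), 0)
  # linear ramp 10*t: triangle of height 70 over 7 h
  expect_equal(compute_auc(grid, 10 * grid), 245)
})

test_that("AUC matches an independent trapezoid (pracma) on random series", {
  skip_if_not_installed("pracma")
  grid <- vas_time_grid()
  withr::with_seed(99, {
    for (i in 1:20) {
      s <- runif(11, 0, 100)
      expect_equal(compute_auc(grid, s), pracma::trapz(grid, s),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is linear and bounded", {
  grid <- vas_time_grid()
  withr::with_seed(1, {
    s1 <- runif(11, 0, 40)
    s2 <- runif(11, 0, 40)
  })
  expect_equal(compute_auc(grid, 0.5 * s1 + 0.25 * s2),
               0.5 * compute_auc(grid, s1) + 0.25 * compute_auc(grid, s2))
  expect_lte(compute_auc(grid, pmin(s1 + s2, 100)), 700)
  expect_gte(compute_auc(grid, s1), 0)
})

test_that("AUC refuses incomplete or invalid series", {
  grid <- vas_time_grid()
  expect_error(compute_auc(grid[-5], (10 * grid)[-5]), "grid")
  expect_error(compute_auc(grid, c(rep(10, 10), 101)), "0, 100")
  expect_error(compute_auc(rev(grid), rep(1, 11)), "increasing")
  # custom grids allowed when the canonical check is disabled
  expect_equal(compute_auc(c(0, 1, 2), c(0, 10, 0), grid = NULL), 10)
})

test_that("binary report counts follow the threshold rule", {
  grid <- vas_time_grid()
  expect_equal(binarize(grid, rep(0, 11), 5), 0)
  expect_equal(binarize(grid, rep(100, 11), 5), 10)
  expect_equal(binarize(grid, c(0, 0, 6, 6, 4, 6, 0, 0, 0, 0, 0), 5), 3)
  # baseline point never counts
  expect_equal(binarize(grid, c(100, rep(0, 10)), 5), 0)
  # monotone non-increasing in the threshold
  withr::with_seed(2, s <- runif(11, 0, 20))
  taus <- seq(0, 25, by = 2.5)
  counts <- vapply(taus, function(tau) binarize(grid, s, tau), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reduce_trial emits one record per subject-period-outcome", {
  trial <- simulate_trial(generative_params(), n_per_group = 5, seed = 4)
  recs <- reduce_trial(trial)
  expect_equal(nrow(recs), 15 * 2 * 4)
  expect_named(recs, c("subject", "group", "period", "received", "told",
                       "outcome", "baseline_mm", "auc_mm_hr", "binary_count"))
  expect_true(all(recs$auc_mm_hr >= 0 & recs$auc_mm_hr <= 700))
  expect_true(all(recs$binary_count %in% 0:10))
  # baseline column is the t = 0 score
  one <- trial[trial$subject == 3 & trial$period == 1 &
                 trial$outcome == "nausea", ]
  expect_equal(recs$baseline_mm[recs$subject == 3 & recs$period == 1 &
                                  recs$outcome == "nausea"],
               one$score_mm[one$time_h == 0])
})

test_that("subjects without a complete crossover are excluded and reported", {
  trial <- simulate_trial(generative_params(), n_per_group = 4, seed = 4)
  maimed <- trial[!(trial$subject == 2 & trial$period == 2), ]
  expect_message(recs <- reduce_trial(maimed), "without a complete crossover")
  expect_false(2 %in% recs$subject)
  expect_equal(attr(recs, "excluded_subjects"), 2L)
  expect_equal(length(unique(recs$subject)), 11)
})

test_that("reduce_trial rejects duplicates and incomplete series", {
  trial <- simulate_trial(generative_params(), n_per_group = 2, seed = 1)
  expect_error(reduce_trial(rbind(trial, trial[1, ])), "Duplicate")
  # a missing timepoint (not a whole period) is an error, not an exclusion
  expect_error(
    reduce_trial(trial[-with(trial, which(subject == 1 & period == 1 &
                                            outcome == "drowsiness" &
                                            time_h == 3))[1], ]),
    "Incomplete VAS series"
  )
})

test_that("empty input reduces to an empty record table with a warning", {
  trial <- simulate_trial(generative_params(), n_per_group = 2, seed = 1)
  expect_warning(recs <- reduce_trial(trial[0, ]), "Empty")
  expect_equal(nrow(recs), 0)
})
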