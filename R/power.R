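#' Per-group sample size for the primary placebo-effect comparison
#'
#' Normal-approximation two-sample sample size for detecting a standardized
#' mean difference between placebo effect-1 (group 1) and placebo effect-2
#' (group 2), inflated for dropout:
#' `n_raw = 2 * (z_{1-alpha/2} + z_{power})^2 / smd^2`, then
#' `n = round(n_raw / (1 - dropout))`. With smd = 0.33, alpha = 0.05,
#' power = 0.80 and 10% dropout this gives 160 per group.
#'
#' @param smd Standardized mean difference (> 0).
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param dropout Anticipated dropout proportion in \[0, 1).
#' @return Integer participants per group.
#' @export
#' @examples
#' sample_size(0.33, 0.05, 0.80, dropout = 0.10) # 160
sample_size <- function(smd, alpha = 0.05, power = 0.80, dropout = 0) {
  if (!is.numeric(smd) || length(smd) != 1 || is.na(smd) || smd <= 0) {
    stop("`smd` must be a positive number.", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1).", call. = FALSE)
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must be in [0, 1).", call. = FALSE)
  }
  n_raw <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / smd^2
  as.integer(round(n_raw / (1 - dropout)))
}

# One simulated trial -> interaction test p-value and drug-effect bias.
simulate_and_test <- function(params, n_per_group, seed, outcome, dropout = 0) {
  trial <- simulate_trial(params, n_per_group = n_per_group,
                          dropout = dropout, seed = seed, outcomes = outcome)
  recs <- suppressMessages(reduce_trial(trial))
  fit_w <- fit_ancova(recs, outcome, "within")
  fit_b <- fit_ancova(recs, outcome, "between")
  p1 <- estimate_effect(fit_w, "placebo_1")
  p2 <- estimate_effect(fit_w, "placebo_2")
  conv <- estimate_effect(fit_w, "conventional_drug")
  model <- estimate_effect(fit_b, "model_drug")
  interaction <- compare_effects(p1, p2, name = "interaction")
  list(p_interaction = interaction$p,
       interaction = interaction$difference,
       bias = conv$estimate - model$estimate)
}

#' Monte Carlo power / type-I error of the interaction test
#'
#' For each sample size in `n_per_group`, simulates `reps` full trials under
#' `params`, runs the estimation pipeline, and records the rejection rate of
#' the placebo-1 vs placebo-2 combined-SE z test at level `alpha` together
#' with the mean bias of the conventional drug estimate relative to the
#' model-estimated drug effect. When the generating interaction is zero the
#' rejection rate is the empirical type-I error.
#'
#' @param params A [generative_params()] object.
#' @param n_per_group Vector of per-group sample sizes.
#' @param reps Simulated trials per sample size.
#' @param seed Master seed; per-replicate seeds are drawn from it, so
#'   results are reproducible.
#' @param outcome Outcome the test is run on (default `"drowsiness"`).
#' @param alpha Test level.
#' @param dropout Dropout fraction passed to the simulator.
#' @return A tibble: `outcome`, `n_per_group`, `reps`, `power`,
#'   `power_mc_se`, `mean_interaction`, `mean_bias`, `bias_mc_se`.
#' @export
#' @examples
#' run_power_experiment(generative_params(), n_per_group = 20, reps = 10,
#'                      seed = 1)
run_power_experiment <- function(params, n_per_group = 160, reps = 200,
                                 seed = 1, outcome = "drowsiness",
                                 alpha = 0.05, dropout = 0) {
  stopifnot(reps >= 1)
  rep_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 2L, reps * length(n_per_group)),
           nrow = reps)
  })
  rows <- lapply(seq_along(n_per_group), function(k) {
    res <- lapply(seq_len(reps), function(r) {
      simulate_and_test(params, n_per_group[k], rep_seeds[r, k], outcome,
                        dropout)
    })
    pvals <- vapply(res, `[[`, numeric(1), "p_interaction")
    ints <- vapply(res, `[[`, numeric(1), "interaction")
    bias <- vapply(res, `[[`, numeric(1), "bias")
    pw <- mean(pvals < alpha)
    tibble::tibble(
      outcome = outcome, n_per_group = n_per_group[k], reps = reps,
      power = pw, power_mc_se = sqrt(pw * (1 - pw) / reps),
      mean_interaction = mean(ints),
      mean_bias = mean(bias), bias_mc_se = stats::sd(bias) / sqrt(reps)
    )
  })
  dplyr::bind_rows(rows)
}

#' Bias of the conventional drug estimate across belief weights
#'
#' The interaction model predicts that the conventional (RPCT) drug
#' estimate exceeds the model-estimated drug effect by `lambda` times the
#' interaction effect, linearly in the belief weight `lambda`. This
#' experiment simulates trials across a `lambda` grid, holding everything
#' else in `params` fixed, and records the mean conventional-minus-model
#' difference per `lambda`; regressing it on `lambda` recovers the
#' generating interaction effect as the slope.
#'
#' @inheritParams run_power_experiment
#' @param lambda_grid Belief weights to scan.
#' @return A tibble: `outcome`, `lambda`, `reps`, `mean_bias`, `bias_mc_se`.
#' @export
run_bias_experiment <- function(params, lambda_grid = c(0, 0.25, 0.5, 0.75, 1),
                                n_per_group = 160, reps = 50, seed = 1,
                                outcome = "drowsiness") {
  rep_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 2L, reps * length(lambda_grid)),
           nrow = reps)
  })
  rows <- lapply(seq_along(lambda_grid), function(k) {
    pk <- params
    pk$lambda <- lambda_grid[k]
    bias <- vapply(seq_len(reps), function(r) {
      simulate_and_test(pk, n_per_group, rep_seeds[r, k], outcome)$bias
    }, numeric(1))
    tibble::tibble(
      outcome = outcome, lambda = lambda_grid[k], reps = reps,
      mean_bias = mean(bias),
      bias_mc_se = if (reps > 1) stats::sd(bias) / sqrt(reps) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
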