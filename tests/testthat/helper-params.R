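# Noise-free calibrated parameters: baselines well inside [0, 100] and all
# variance components zero, so clamping is inert and the cell-mean identities
# hold exactly.
zero_noise_params <- function(lambda = 0.5) {
  eff <- default_effect_table()
  eff$baseline_sd <- 0
  generative_params(effects = eff, lambda = lambda,
                    sigma_subject = 0, sigma_resid = 0)
}

# All effect magnitudes and the period effect zero.
null_params <- function(sigma_subject = 0, sigma_resid = 0, baseline_sd = 0) {
  eff <- default_effect_table()
  eff$drug_auc <- 0
  eff$placebo_auc <- 0
  eff$interaction_auc <- 0
  eff$period_auc <- 0
  eff$baseline_mean <- 50  # far from both VAS bounds
  eff$baseline_sd <- baseline_sd
  generative_params(effects = eff, sigma_subject = sigma_subject,
                    sigma_resid = sigma_resid)
}

small_noisy_records <- function(n_per_group = 12, seed = 42) {
  p <- generative_params()
  reduce_trial(simulate_trial(p, n_per_group = n_per_group, seed = seed))
}
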