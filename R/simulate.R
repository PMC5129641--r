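#' Expected VAS score under the additive interaction model
#'
#' The interaction model treats the received-placebo/told-placebo cell as
#' the reference (non-specific passive changes only) and adds, on top of a
#' subject's baseline level: a drug effect when drug is received, a placebo
#' effect weighted by the belief factor, and a drug*placebo interaction
#' effect when drug is received *and* the belief factor is positive. The
#' belief factor is 1 when told drug, 0 when told placebo, and `lambda`
#' when told "unknown" (the RPCT arms), so conventionally estimated drug
#' effects absorb a `lambda` share of the interaction. A period effect is
#' added to post-dose scores in period 2. Scores are clamped to the 0-100 mm
#' VAS range.
#'
#' @param params A [generative_params()] object.
#' @param outcome Outcome name (a row of `params$effects`).
#' @param received `"H"` or `"P"`.
#' @param told `"H"`, `"P"`, or `"U"`.
#' @param period 1 or 2.
#' @param t Time(s) in hours; must lie on [vas_time_grid()].
#' @param subject_baseline The subject's baseline symptom level in mm.
#' @return Expected score(s) in mm, same length as `t`.
#' @export
#' @examples
#' p <- generative_params()
#' expected_score(p, "drowsiness", "H", "U", 1, vas_time_grid(), 5)
expected_score <- function(params, outcome, received, told, period, t,
                           subject_baseline) {
  stopifnot(inherits(params, "bp_params"))
  eff <- params$effects[params$effects$outcome == outcome, ]
  if (nrow(eff) != 1) stop("Unknown outcome: ", outcome, call. = FALSE)
  if (!received %in% received_levels()) {
    stop("`received` must be \"H\" or \"P\".", call. = FALSE)
  }
  if (!told %in% told_levels()) {
    stop("`told` must be \"H\", \"P\", or \"U\".", call. = FALSE)
  }
  if (!period %in% c(1, 2)) stop("`period` must be 1 or 2.", call. = FALSE)
  grid <- vas_time_grid()
  idx <- match(t, grid)
  if (anyNA(idx)) {
    stop("`t` must lie on the 11-point measurement grid.", call. = FALSE)
  }

  b <- switch(told, H = 1, P = 0, U = params$lambda)
  r <- as.numeric(received == "H")
  mag <- effect_magnitudes(params, outcome)
  mean_score <- subject_baseline +
    (eff$period_auc / profile_auc(params$profile_placebo)) *
      as.numeric(period == 2) * as.numeric(t > 0) +
    mag$drug_mm * as.numeric(params$profile_drug)[idx] * r +
    mag$placebo_mm * as.numeric(params$profile_placebo)[idx] * b +
    mag$interaction_mm * as.numeric(params$profile_interaction)[idx] * r * b
  clamp01(mean_score)
}

# Per-timepoint magnitudes (mm) implied by the AUC-scale effect sizes.
effect_magnitudes <- function(params, outcome) {
  eff <- params$effects[params$effects$outcome == outcome, ]
  list(
    drug_mm = eff$drug_auc / profile_auc(params$profile_drug),
    placebo_mm = eff$placebo_auc / profile_auc(params$profile_placebo),
    interaction_mm = eff$interaction_auc / profile_auc(params$profile_interaction)
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 100)

#' Simulate a hybrid balanced-placebo / RPCT crossover trial
#'
#' Block-randomizes `3 * n_per_group` participants to the six crossover
#' assignments ([generate_schedule()]), then generates per-subject VAS time
#' courses for each outcome under the additive interaction model
#' ([expected_score()]). Each subject carries a random intercept
#' (`sigma_subject`) shared across both periods; every observation receives
#' independent residual noise (`sigma_resid` post-dose, the outcome's
#' `baseline_sd` at t = 0). Scores are clamped to \[0, 100\] after noise.
#' A `dropout` fraction of subjects, drawn at random, lose their period-2
#' measurements (mirroring participants lost to crossover, who are excluded
#' from analysis by [reduce_trial()]).
#'
#' All randomness flows from `seed` in a fixed order (schedule, subject
#' intercepts, baselines, residuals, dropout), so equal seeds give
#' identical trials.
#'
#' @param params A [generative_params()] object.
#' @param n_per_group Participants per randomization group (>= 2).
#' @param dropout Fraction in \[0, 1) of subjects losing period 2. Default 0.
#' @param seed Integer seed.
#' @param outcomes Optional character subset of outcomes to simulate
#'   (default: all rows of `params$effects`).
#' @return A `bp_trial`: a long tibble with columns `subject`, `group`,
#'   `period`, `received`, `told`, `outcome`, `time_h`, `score_mm`, with the
#'   generating `params` attached as attribute `"params"`.
#' @export
#' @examples
#' trial <- simulate_trial(generative_params(), n_per_group = 4, seed = 1)
#' dplyr::count(trial, group, received, told)
simulate_trial <- function(params, n_per_group = 160, dropout = 0, seed = 1,
                           outcomes = NULL) {
  stopifnot(inherits(params, "bp_params"))
  if (!is.numeric(n_per_group) || length(n_per_group) != 1 || n_per_group < 2) {
    stop("`n_per_group` must be an integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(dropout) || length(dropout) != 1 || is.na(dropout) ||
      dropout < 0 || dropout >= 1) {
    stop("`dropout` must be a proportion in [0, 1).", call. = FALSE)
  }
  eff <- params$effects
  if (!is.null(outcomes)) {
    if (!all(outcomes %in% eff$outcome)) {
      stop("Unknown outcome(s): ",
           paste(setdiff(outcomes, eff$outcome), collapse = ", "),
           call. = FALSE)
    }
    eff <- eff[eff$outcome %in% outcomes, ]
  }
  n_subj <- as.integer(3 * n_per_group)
  grid <- vas_time_grid()
  n_t <- length(grid)

  sched <- generate_schedule(n_subj, block_size = 6, seed = seed)

  withr::with_seed(seed + 1L, {
    # Per subject-period condition vectors, subjects ordered by slot.
    received <- c(rbind(sched$period1_received, sched$period2_received))
    told <- c(rbind(sched$period1_told, sched$period2_told))
    subject <- rep(seq_len(n_subj), each = 2L)
    group <- rep(sched$group, each = 2L)
    period <- rep(1:2, times = n_subj)
    n_sp <- length(subject)  # subject-periods

    prof_d <- as.numeric(params$profile_drug)
    prof_p <- as.numeric(params$profile_placebo)
    prof_i <- as.numeric(params$profile_interaction)
    a_p <- profile_auc(params$profile_placebo)
    b_fac <- ifelse(told == "H", 1, ifelse(told == "P", 0, params$lambda))
    r_fac <- as.numeric(received == "H")
    post <- as.numeric(grid > 0)

    pieces <- vector("list", nrow(eff))
    for (k in seq_len(nrow(eff))) {
      e <- eff[k, ]
      mag <- effect_magnitudes(params, e$outcome)
      u <- rnorm(n_subj, 0, params$sigma_subject)[subject]
      # n_sp x n_t matrix of expected scores
      mu <- matrix(e$baseline_mean + u, n_sp, n_t) +
        outer((e$period_auc / a_p) * as.numeric(period == 2), post) +
        outer(mag$drug_mm * r_fac, prof_d) +
        outer(mag$placebo_mm * b_fac, prof_p) +
        outer(mag$interaction_mm * r_fac * b_fac, prof_i)
      noise_sd <- rep(c(e$baseline_sd, rep(params$sigma_resid, n_t - 1L)),
                      each = n_sp)
      score <- clamp01(mu + matrix(rnorm(n_sp * n_t, 0, noise_sd), n_sp, n_t))
      pieces[[k]] <- tibble::tibble(
        subject = rep(subject, times = n_t),
        group = rep(group, times = n_t),
        period = rep(period, times = n_t),
        received = rep(received, times = n_t),
        told = rep(told, times = n_t),
        outcome = e$outcome,
        time_h = rep(grid, each = n_sp),
        score_mm = as.vector(score)
      )
    }
    trial <- dplyr::bind_rows(pieces)

    if (dropout > 0) {
      lost <- which(runif(n_subj) < dropout)
      if (length(lost)) {
        trial <- trial[!(trial$subject %in% lost & trial$period == 2L), ]
      }
    }
  })

  trial <- dplyr::arrange(trial, .data$outcome, .data$subject, .data$period,
                          .data$time_h)
  attr(trial, "params") <- params
  class(trial) <- c("bp_trial", class(trial))
  trial
}
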