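#' Build an effect estimate from reported numbers
#'
#' Constructs a one-row effect-estimate tibble compatible with
#' [compare_effects()] from a point estimate and either a standard error or
#' a symmetric 95% CI (from which `se = (ci_high - ci_low) / (2 * 1.96)` is
#' recovered). Useful for re-deriving published comparisons from printed
#' tables.
#'
#' @param effect,outcome Labels.
#' @param estimate Point estimate (mm*hr).
#' @param se Standard error; omit to derive from the CI.
#' @param ci_low,ci_high 95% CI bounds; omitted bounds are derived from `se`.
#' @return A one-row tibble matching [estimate_effect()] output.
#' @export
#' @examples
#' effect_estimate("placebo_1", "drowsiness", 75.9, ci_low = 50.8, ci_high = 101.0)
effect_estimate <- function(effect, outcome, estimate, se = NULL,
                            ci_low = NULL, ci_high = NULL) {
  if (is.null(se)) {
    if (is.null(ci_low) || is.null(ci_high)) {
      stop("Provide `se` or both CI bounds.", call. = FALSE)
    }
    se <- (ci_high - ci_low) / (2 * z_crit())
  }
  if (se < 0) stop("`se` must be >= 0.", call. = FALSE)
  if (is.null(ci_low)) ci_low <- estimate - z_crit() * se
  if (is.null(ci_high)) ci_high <- estimate + z_crit() * se
  zval <- if (se > 0) estimate / se else if (estimate == 0) 0 else
    sign(estimate) * Inf
  tibble::tibble(
    outcome = outcome, effect = effect, scope = NA_character_,
    estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
    z = zval, p = 2 * stats::pnorm(-abs(zval))
  )
}

#' Compare two effect estimates by the z test
#'
#' Tests the difference between two (independently estimated) effects using
#' the combined standard error `sqrt(se_a^2 + se_b^2)` — the square root of
#' the sum of squares of the separate standard errors — with a two-sided
#' normal reference. This is how the drug*placebo interaction effect is
#' tested (placebo effect-1 vs placebo effect-2) and how conventional and
#' model-estimated drug effects are compared. Comparisons whose effects
#' share a condition cell (e.g. total vs model drug, both using P/P) ignore
#' that covariance; such results carry `independent = FALSE`.
#'
#' @param a,b One-row effect-estimate tibbles ([estimate_effect()] or
#'   [effect_estimate()]); must refer to the same outcome.
#' @param name Optional comparison label (default `"a_minus_b"` style).
#' @param independent Set `FALSE` to flag comparisons between estimates that
#'   share data.
#' @return A one-row tibble: `comparison`, `outcome`, `difference`,
#'   `combined_se`, `ci_low`, `ci_high`, `z`, `p`, `independent`.
#' @export
#' @examples
#' a <- effect_estimate("placebo_1", "drowsiness", 75.9, ci_low = 50.8, ci_high = 101.0)
#' b <- effect_estimate("placebo_2", "drowsiness", 40.8, ci_low = 24.9, ci_high = 56.7)
#' compare_effects(a, b, name = "interaction")
compare_effects <- function(a, b, name = NULL, independent = TRUE) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (!identical(a$outcome, b$outcome)) {
    stop("Effects must refer to the same outcome.", call. = FALSE)
  }
  if (is.null(name)) name <- paste0(a$effect, "_minus_", b$effect)
  diff <- a$estimate - b$estimate
  cse <- sqrt(a$se^2 + b$se^2)
  if (cse == 0) {
    if (diff == 0) {
      zval <- 0
    } else {
      warning("Zero combined SE with nonzero difference: z is infinite.",
              call. = FALSE)
      zval <- sign(diff) * Inf
    }
  } else {
    zval <- diff / cse
  }
  tibble::tibble(
    comparison = name, outcome = a$outcome, difference = diff,
    combined_se = cse,
    ci_low = diff - z_crit() * cse, ci_high = diff + z_crit() * cse,
    z = zval, p = if (is.nan(zval)) NA_real_ else 2 * stats::pnorm(-abs(zval)),
    independent = independent
  )
}

#' Decompose effects into interaction and bias metrics
#'
#' Completes a six-effect table (per outcome) with the derived quantities
#' of the interaction model:
#' * `interaction` — placebo effect-1 minus placebo effect-2, tested with
#'   the combined-SE z test (the design's primary contrast);
#' * `additivity_gap` — total minus (model drug + placebo effect-2), the
#'   departure of the total effect from additivity (equal to the
#'   interaction in expectation);
#' * `overestimation_pct` — `100 * (conventional - model) / model`, the
#'   relative bias of the conventional RPCT drug estimate;
#' * `interaction_share_pct` — `100 * interaction / total`.
#'
#' Percentages are stored unrounded and set to `NA` when their denominator
#' is zero or missing; the print method rounds to integers for display.
#'
#' @param effects Effect table from [estimate_all()] (or assembled with
#'   [effect_estimate()]); needs effects `placebo_1`, `placebo_2`,
#'   `model_drug`, `conventional_drug`, `total` per outcome.
#' @return A `bp_decomposition`: list with the input `effects`, a
#'   `comparisons` tibble (interaction, conventional-vs-model,
#'   additivity gap per outcome) and a `metrics` tibble.
#' @export
#' @examples
#' eff <- hydroxyzine_trial_estimates() |>
#'   dplyr::mutate(scope = NA_character_, z = estimate / se,
#'                 p = 2 * pnorm(-abs(z)))
#' decompose_effects(eff)
decompose_effects <- function(effects) {
  stopifnot(all(c("outcome", "effect", "estimate", "se") %in% names(effects)))
  outs <- unique(effects$outcome)
  comp_rows <- list()
  met_rows <- list()
  for (o in outs) {
    e <- effects[effects$outcome == o, ]
    pick <- function(nm) {
      row <- e[e$effect == nm, ]
      if (nrow(row) != 1 || is.na(row$estimate)) NULL else row
    }
    p1 <- pick("placebo_1"); p2 <- pick("placebo_2")
    md <- pick("model_drug"); cv <- pick("conventional_drug")
    tot <- pick("total")

    interaction <- if (!is.null(p1) && !is.null(p2)) {
      compare_effects(p1, p2, name = "interaction")
    }
    conv_vs_model <- if (!is.null(cv) && !is.null(md)) {
      compare_effects(cv, md, name = "conventional_vs_model")
    }
    gap <- if (!is.null(tot) && !is.null(md) && !is.null(p2)) {
      sum_est <- effect_estimate(
        "model_drug_plus_placebo_2", o,
        estimate = md$estimate + p2$estimate,
        se = sqrt(md$se^2 + p2$se^2)
      )
      compare_effects(tot, sum_est, name = "additivity_gap",
                      independent = FALSE)
    }
    comp_rows[[o]] <- dplyr::bind_rows(interaction, conv_vs_model, gap)

    interaction_est <- if (is.null(interaction)) NA_real_ else
      interaction$difference
    total_est <- if (is.null(tot)) NA_real_ else tot$estimate
    met_rows[[o]] <- tibble::tibble(
      outcome = o,
      interaction = interaction_est,
      total = total_est,
      additivity_gap = if (is.null(gap)) NA_real_ else gap$difference,
      effect_sum = if (is.null(md) || is.null(p2)) NA_real_ else
        md$estimate + p2$estimate,
      overestimation_pct = if (is.null(cv) || is.null(md) ||
                               md$estimate == 0) NA_real_ else
        100 * (cv$estimate - md$estimate) / md$estimate,
      interaction_share_pct = if (is.na(interaction_est) || is.na(total_est) ||
                                  total_est == 0) NA_real_ else
        100 * interaction_est / total_est
    )
  }
  structure(
    list(
      effects = tibble::as_tibble(effects),
      comparisons = dplyr::bind_rows(comp_rows),
      metrics = dplyr::bind_rows(met_rows)
    ),
    class = "bp_decomposition"
  )
}

#' @export
print.bp_decomposition <- function(x, digits = 1, ...) {
  cat("<bp_decomposition> drug*placebo interaction decomposition\n\n")
  fmt <- function(est, lo, hi, p) {
    sprintf("%.*f mm*hr (%.*f to %.*f, p = %s)", digits, est, digits, lo,
            digits, hi, format.pval(p, digits = 2, eps = 1e-3))
  }
  for (o in unique(x$metrics$outcome)) {
    cat("==", o, "==\n")
    e <- x$effects[x$effects$outcome == o, ]
    for (i in seq_len(nrow(e))) {
      if (is.na(e$estimate[i])) next
      cat(sprintf("  %-22s %s\n", e$effect[i],
                  fmt(e$estimate[i], e$ci_low[i], e$ci_high[i], e$p[i])))
    }
    cmp <- x$comparisons[x$comparisons$outcome == o, ]
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("  %-22s %s\n", cmp$comparison[i],
                  fmt(cmp$difference[i], cmp$ci_low[i], cmp$ci_high[i],
                      cmp$p[i])))
    }
    m <- x$metrics[x$metrics$outcome == o, ]
    if (!is.na(m$overestimation_pct)) {
      cat(sprintf("  conventional overestimates model drug effect by ~%d%%\n",
                  round(m$overestimation_pct)))
    }
    if (!is.na(m$interaction_share_pct)) {
      cat(sprintf("  interaction is ~%d%% of the total effect\n",
                  round(m$interaction_share_pct)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Non-parametric secondary test of one effect
#'
#' Secondary analysis on unadjusted AUCs: within-group effects
#' (`placebo_1`, `placebo_2`, `conventional_drug`) use the Wilcoxon
#' signed-rank test on the per-subject paired difference between the two
#' conditions of the crossover; between-group effects use the Wilcoxon
#' rank-sum test on the two cells' AUCs (one observation per subject).
#' Exact p-values are used for n <= 25, the normal approximation otherwise.
#'
#' @param records Records from [reduce_trial()].
#' @param effect Effect name (see [estimate_effect()]).
#' @param outcome Outcome name.
#' @return A one-row tibble: `outcome`, `effect`, `test`, `statistic`, `p`,
#'   `n`.
#' @export
nonparametric_effect <- function(records, effect, outcome) {
  cat_row <- effect_catalog()[effect_catalog()$effect == effect, ]
  if (nrow(cat_row) != 1) stop("Unknown effect: ", effect, call. = FALSE)
  d <- records[records$outcome == outcome, ]
  if (nrow(d) == 0) stop("No records for outcome: ", outcome, call. = FALSE)
  d$condition <- condition_label(d$received, d$told)

  if (cat_row$scope == "within") {
    wide <- tidyr::pivot_wider(
      d[d$condition %in% c(cat_row$cell_a, cat_row$cell_b),
        c("subject", "condition", "auc_mm_hr")],
      names_from = "condition", values_from = "auc_mm_hr"
    )
    wide <- wide[stats::complete.cases(wide), ]
    diffs <- wide[[cat_row$cell_a]] - wide[[cat_row$cell_b]]
    n <- length(diffs)
    if (n == 0) stop("No paired data for effect ", effect, call. = FALSE)
    if (all(diffs == 0)) {
      warning("All paired differences are zero; p = 1.", call. = FALSE)
      return(tibble::tibble(outcome = outcome, effect = effect,
                            test = "signed-rank", statistic = NA_real_,
                            p = 1, n = n))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(diffs, exact = n <= 25, correct = TRUE)
    )
    tibble::tibble(outcome = outcome, effect = effect, test = "signed-rank",
                   statistic = unname(wt$statistic), p = wt$p.value, n = n)
  } else {
    xa <- d$auc_mm_hr[d$condition == cat_row$cell_a]
    xb <- d$auc_mm_hr[d$condition == cat_row$cell_b]
    if (!length(xa) || !length(xb)) {
      stop("Missing cells for effect ", effect, call. = FALSE)
    }
    n <- min(length(xa), length(xb))
    wt <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = n <= 25, correct = TRUE)
    )
    tibble::tibble(outcome = outcome, effect = effect, test = "rank-sum",
                   statistic = unname(wt$statistic), p = wt$p.value,
                   n = length(xa) + length(xb))
  }
}

#' Rank correlations of placebo effects across outcomes
#'
#' Computes per-subject unadjusted placebo-effect differences (told-drug
#' minus told-placebo AUC within the crossover) separately for group 1
#' (placebo effect-1, drug receivers) and group 2 (placebo effect-2,
#' placebo receivers), then Spearman rank correlations between all outcome
#' pairs within each group.
#'
#' @param records Records from [reduce_trial()].
#' @return A tibble: `effect`, `outcome_a`, `outcome_b`, `rho`, `p`, `n`.
#' @export
placebo_correlations <- function(records) {
  d <- records
  d$condition <- condition_label(d$received, d$told)
  per_subject <- d[d$condition %in% c("H/H", "H/P", "P/H", "P/P"), ] |>
    dplyr::mutate(told_drug = .data$told == "H") |>
    dplyr::summarise(
      diff = .data$auc_mm_hr[.data$told_drug] -
        .data$auc_mm_hr[!.data$told_drug],
      .by = c("group", "subject", "outcome")
    )
  rows <- list()
  for (g in c(1L, 2L)) {
    eff_name <- if (g == 1L) "placebo_1" else "placebo_2"
    wide <- tidyr::pivot_wider(per_subject[per_subject$group == g, ],
                               names_from = "outcome", values_from = "diff")
    outs <- setdiff(names(wide), c("group", "subject"))
    if (length(outs) < 2) next
    for (i in seq_len(length(outs) - 1)) {
      for (j in (i + 1):length(outs)) {
        x <- wide[[outs[i]]]; y <- wide[[outs[j]]]
        ok <- stats::complete.cases(x, y)
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman")
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          effect = eff_name, outcome_a = outs[i], outcome_b = outs[j],
          rho = unname(ct$estimate), p = ct$p.value, n = sum(ok)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
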