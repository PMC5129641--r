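#' Fit the crossover ANCOVA for one outcome
#'
#' Fits the analysis-of-covariance model behind the effect contrasts: AUC
#' regressed on an intercept, the period-specific baseline score, period,
#' and intervention condition — plus group and subject-nested-within-group
#' terms (as fixed effects) for the within-group scope used by the paired
#' contrasts.
#'
#' `scope = "between"` fits ordinary least squares on the pooled records
#' with the six-level condition factor (reference cell P/P), giving the
#' between-group contrasts (model-estimated drug, total, drug+interaction).
#'
#' `scope = "within"` additionally conditions on subject. Subject (and
#' hence group) fixed effects are absorbed exactly by within-subject
#' centering of the response and regressors; because each subject
#' contributes one pair of conditions, only the within-pair condition
#' contrast is identifiable per group, coded against a per-group reference
#' cell (told-placebo in groups 1-2, received-placebo in group 3). The
#' residual degrees of freedom account for the absorbed subject
#' parameters. This is algebraically identical to the full dummy-variable
#' least-squares fit with subject effects.
#'
#' @param records Outcome records from [reduce_trial()].
#' @param outcome Outcome to fit.
#' @param scope `"between"` or `"within"`.
#' @param response `"auc_mm_hr"` (default) or `"binary_count"` — the binary
#'   secondary outcome uses the same linear contrast machinery.
#' @return A `bp_ancova` object with elements `coef`, `vcov`, `df`,
#'   `sigma2`, `n`, `scope`, `outcome`, `aliased`.
#' @export
#' @examples
#' trial <- simulate_trial(generative_params(), n_per_group = 12, seed = 1)
#' fit <- fit_ancova(reduce_trial(trial), "drowsiness", "between")
#' coef(fit)
fit_ancova <- function(records, outcome,
                       scope = c("between", "within"),
                       response = c("auc_mm_hr", "binary_count")) {
  scope <- match.arg(scope)
  response <- match.arg(response)
  d <- records[records$outcome == outcome, ]
  if (nrow(d) == 0) stop("No records for outcome: ", outcome, call. = FALSE)
  if (anyNA(d$baseline_mm)) {
    stop("Baseline missing for some records.", call. = FALSE)
  }
  d$condition <- condition_label(d$received, d$told)
  if (length(unique(d$condition)) < 2) {
    stop("Need at least 2 condition levels to fit contrasts.", call. = FALSE)
  }
  y <- d[[response]]

  if (scope == "between") {
    present <- intersect(condition_levels(), unique(d$condition))
    d$condition <- factor(d$condition, levels = present)
    d$period <- factor(d$period, levels = c(1, 2))
    fit <- stats::lm(y ~ baseline_mm + period + condition, data = d)
    cf <- stats::coef(fit)
    aliased <- names(cf)[is.na(cf)]
    bad_cond <- grep("^condition", aliased, value = TRUE)
    if (length(bad_cond)) {
      stop("Rank-deficient design; collinear terms: ",
           paste(bad_cond, collapse = ", "), call. = FALSE)
    }
    keep <- !is.na(cf)
    out <- list(
      coef = cf[keep],
      vcov = suppressWarnings(stats::vcov(fit))[names(cf)[keep], names(cf)[keep]],
      df = fit$df.residual, sigma2 = sum(stats::resid(fit)^2) / fit$df.residual,
      n = nrow(d), scope = scope, outcome = outcome, response = response,
      aliased = aliased, lm = fit, cells = levels(d$condition)
    )
    return(structure(out, class = "bp_ancova"))
  }

  # within scope: absorb subject fixed effects by within-subject centering
  tab <- table(d$subject)
  if (!any(tab >= 2)) {
    stop("Within-scope ANCOVA needs repeated subjects (both periods).",
         call. = FALSE)
  }
  d <- d[d$subject %in% names(tab)[tab >= 2], ]
  y <- d[[response]]
  # one coded contrast cell per group (reference: H/P, P/P, P/U); cells
  # absent from the data contribute no column
  coded <- intersect(c("H/H", "P/H", "H/U"), unique(d$condition))
  X <- cbind(
    baseline_mm = d$baseline_mm,
    period2 = as.numeric(d$period == 2)
  )
  for (cl in coded) {
    X <- cbind(X, as.numeric(d$condition == cl))
    colnames(X)[ncol(X)] <- paste("condition", cl)
  }
  subj <- as.integer(factor(d$subject))
  n_subj <- max(subj)
  center <- function(v) v - (rowsum(v, subj) / as.vector(table(subj)))[subj, ]
  Xc <- apply(X, 2, center)
  yc <- center(y)
  keep <- apply(Xc, 2, function(v) sqrt(mean(v^2)) > 1e-10)
  aliased <- colnames(X)[!keep]
  if (any(grepl("^condition", aliased))) {
    stop("Rank-deficient within-subject design; collinear terms: ",
         paste(grep("^condition", aliased, value = TRUE), collapse = ", "),
         call. = FALSE)
  }
  Xc <- Xc[, keep, drop = FALSE]
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) {
    drop_cols <- colnames(Xc)[qr_x$pivot[(qr_x$rank + 1):ncol(Xc)]]
    stop("Rank-deficient within-subject design; collinear terms: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, yc)
  rss <- sum((yc - Xc %*% beta)^2)
  df <- nrow(Xc) - n_subj - ncol(Xc)
  if (df <= 0) stop("Non-positive residual degrees of freedom.", call. = FALSE)
  sigma2 <- rss / df
  vc <- sigma2 * solve(crossprod(Xc))
  dimnames(vc) <- list(colnames(Xc), colnames(Xc))
  structure(
    list(coef = beta, vcov = vc, df = df, sigma2 = sigma2, n = nrow(Xc),
         n_subjects = n_subj, scope = scope, outcome = outcome,
         response = response, aliased = aliased,
         cells = intersect(condition_levels(), unique(d$condition))),
    class = "bp_ancova"
  )
}

#' @export
coef.bp_ancova <- function(object, ...) object$coef

#' @export
vcov.bp_ancova <- function(object, ...) object$vcov

#' @export
print.bp_ancova <- function(x, ...) {
  cat(sprintf("<bp_ancova> %s-scope ANCOVA for %s (%s), n = %d, df = %d\n",
              x$scope, x$outcome, x$response, x$n, x$df))
  print(round(x$coef, 4))
  invisible(x)
}

# effect name -> (scope, contrast cells)
effect_catalog <- function() {
  tibble::tribble(
    ~effect,                 ~scope,    ~cell_a, ~cell_b,
    "placebo_1",             "within",  "H/H",   "H/P",
    "placebo_2",             "within",  "P/H",   "P/P",
    "conventional_drug",     "within",  "H/U",   "P/U",
    "model_drug",            "between", "H/P",   "P/P",
    "total",                 "between", "H/H",   "P/P",
    "drug_plus_interaction", "between", "H/H",   "P/H"
  )
}

#' Estimate one of the six effects from a fitted ANCOVA
#'
#' The six named effects of the interaction model are contrasts between
#' condition cells:
#' * `placebo_1` = H/H - H/P (placebo + interaction; within group 1)
#' * `placebo_2` = P/H - P/P (placebo only; within group 2)
#' * `conventional_drug` = H/U - P/U (drug + a belief-weighted share of the
#'   interaction; within group 3 — the RPCT estimate)
#' * `model_drug` = H/P - P/P (drug only; between groups)
#' * `total` = H/H - P/P (drug + placebo + interaction; between groups)
#' * `drug_plus_interaction` = H/H - P/H (between groups)
#'
#' Point estimates are contrasts of adjusted means; standard errors come
#' from the coefficient variance matrix under the contrast vector, with
#' normal-reference (z) CIs and p-values.
#'
#' @param fit A `bp_ancova` from [fit_ancova()], of the scope the effect
#'   requires (see above); requesting e.g. a within-scope effect from a
#'   between-scope fit is an error.
#' @param effect Effect name.
#' @return A one-row tibble: `outcome`, `effect`, `scope`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `z`, `p`.
#' @export
estimate_effect <- function(fit, effect) {
  stopifnot(inherits(fit, "bp_ancova"))
  cat_row <- effect_catalog()[effect_catalog()$effect == effect, ]
  if (nrow(cat_row) != 1) {
    stop("Unknown effect: ", effect, "; see effect_catalog().", call. = FALSE)
  }
  if (cat_row$scope != fit$scope) {
    stop(sprintf("Effect \"%s\" requires a %s-scope fit (got %s).",
                 effect, cat_row$scope, fit$scope), call. = FALSE)
  }
  cells_needed <- c(cat_row$cell_a, cat_row$cell_b)
  if (!all(cells_needed %in% fit$cells)) {
    stop(sprintf("Cells %s not present in the fitted data.",
                 paste(setdiff(cells_needed, fit$cells), collapse = ", ")),
         call. = FALSE)
  }

  cvec <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
  term_of <- function(cell) {
    if (fit$scope == "between") paste0("condition", cell)
    else paste("condition", cell)
  }
  for (w in c(1, -1)) {
    cell <- if (w == 1) cat_row$cell_a else cat_row$cell_b
    trm <- term_of(cell)
    if (trm %in% names(cvec)) cvec[trm] <- cvec[trm] + w
    # reference cells (P/P between; H/P, P/P, P/U within) contribute zero
  }
  est <- sum(cvec * fit$coef)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  zval <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  tibble::tibble(
    outcome = fit$outcome, effect = effect, scope = fit$scope,
    estimate = est, se = se,
    ci_low = est - z_crit() * se, ci_high = est + z_crit() * se,
    z = zval, p = 2 * stats::pnorm(-abs(zval))
  )
}

#' Estimate all six effects for every outcome
#'
#' Fits the between- and within-scope ANCOVA for each outcome in `records`
#' and evaluates the six effect contrasts. Outcomes or effects whose cells
#' are missing yield `NA` rows (with a warning) rather than failing the
#' whole table.
#'
#' @inheritParams fit_ancova
#' @param outcomes Optional subset of outcomes.
#' @return A tibble with one row per outcome x effect (see
#'   [estimate_effect()] for columns).
#' @export
#' @examples
#' trial <- simulate_trial(generative_params(), n_per_group = 12, seed = 1)
#' estimate_all(reduce_trial(trial))
estimate_all <- function(records, outcomes = NULL,
                         response = c("auc_mm_hr", "binary_count")) {
  response <- match.arg(response)
  if (is.null(outcomes)) outcomes <- unique(records$outcome)
  cat_tbl <- effect_catalog()
  rows <- list()
  for (o in outcomes) {
    fits <- list()
    for (sc in c("between", "within")) {
      fits[[sc]] <- tryCatch(fit_ancova(records, o, sc, response),
                             error = function(e) e)
    }
    for (i in seq_len(nrow(cat_tbl))) {
      eff <- cat_tbl$effect[i]
      fit <- fits[[cat_tbl$scope[i]]]
      row <- if (inherits(fit, "error")) {
        fit
      } else {
        tryCatch(estimate_effect(fit, eff), error = function(e) e)
      }
      if (inherits(row, "error")) {
        warning(sprintf("%s / %s: %s", o, eff, conditionMessage(row)),
                call. = FALSE)
        row <- tibble::tibble(
          outcome = o, effect = eff, scope = cat_tbl$scope[i],
          estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, z = NA_real_, p = NA_real_
        )
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  out$effect <- factor(out$effect, levels = cat_tbl$effect)
  dplyr::arrange(out, match(.data$outcome, outcomes), .data$effect) |>
    dplyr::mutate(effect = as.character(.data$effect))
}
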