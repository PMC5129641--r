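# Independent least-squares oracle for the crossover ANCOVA, written as
# explicit normal equations on the full dummy-variable design matrix
# (including subject fixed effects for the within scope). Used to check
# fit_ancova(), which absorbs subject effects by centering instead.
ancova_oracle <- function(records, outcome, scope) {
  d <- records[records$outcome == outcome, ]
  d <- d[order(d$subject, d$period), ]
  cond <- paste(d$received, d$told, sep = "/")
  y <- d$auc_mm_hr

  if (scope == "between") {
    X <- cbind(
      intercept = 1,
      baseline_mm = d$baseline_mm,
      period2 = as.numeric(d$period == 2)
    )
    lv <- setdiff(intersect(condition_levels(), unique(cond)), "P/P")
    for (cl in lv) X <- cbind(X, as.numeric(cond == cl))
    colnames(X)[(ncol(X) - length(lv) + 1):ncol(X)] <- lv
    contrast_terms <- list(
      model_drug = c("H/P"), total = c("H/H"),
      drug_plus_interaction = c("H/H", "P/H")
    )
    contrast_signs <- list(model_drug = 1, total = 1,
                           drug_plus_interaction = c(1, -1))
  } else {
    subj <- factor(d$subject)
    S <- stats::model.matrix(~ subj)[, -1, drop = FALSE] # subjects absorb group
    X <- cbind(
      intercept = 1,
      baseline_mm = d$baseline_mm,
      period2 = as.numeric(d$period == 2),
      `H/H` = as.numeric(cond == "H/H"),
      `P/H` = as.numeric(cond == "P/H"),
      `H/U` = as.numeric(cond == "H/U"),
      S
    )
    contrast_terms <- list(placebo_1 = "H/H", placebo_2 = "P/H",
                           conventional_drug = "H/U")
    contrast_signs <- list(placebo_1 = 1, placebo_2 = 1,
                           conventional_drug = 1)
  }

  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  df <- nrow(X) - ncol(X)
  vcv <- drop(rss / df) * solve(xtx)

  out <- list()
  for (nm in names(contrast_terms)) {
    cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
    cvec[contrast_terms[[nm]]] <- contrast_signs[[nm]]
    out[[nm]] <- list(
      estimate = drop(crossprod(cvec, beta)),
      se = drop(sqrt(t(cvec) %*% vcv %*% cvec))
    )
  }
  out$df <- df
  out
}

# Exact two-sided signed-rank p-value by enumerating all sign patterns.
signed_rank_enumeration_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
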