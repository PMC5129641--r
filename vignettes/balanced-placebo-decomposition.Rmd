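---
title: "Decomposing drug, placebo, and drug*placebo interaction effects in a hybrid balanced-placebo crossover design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing drug, placebo, and drug*placebo interaction effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpcross)
library(dplyr)
```

## The scientific problem

A randomized placebo-controlled trial (RPCT) estimates a drug effect as the
difference between its medication and placebo arms. That interpretation
assumes the drug effect and the placebo effect (the meaning response driven
by the belief of receiving an active drug) are *additive*. If belief and
pharmacology interact — a drug*placebo interaction, or effect modification —
the interaction is confined to the medication arm, and the conventional
difference is a biased estimate of the pharmacological effect.

The balanced placebo design separates the two by crossing what a participant
*receives* (drug `H` or placebo `P`) with what they are *told* they receive
(`H` or `P`). A hybrid design adds the conventional RPCT cells, in which
participants are told the assignment is *unknown* (`U`, a 50/50 chance).
`bpcross` implements this hybrid design as three two-period crossover arms:

* **Group 1** receives drug in both periods, told drug in one and placebo in
  the other (cells `H/H`, `H/P`);
* **Group 2** receives placebo in both periods with the same told crossover
  (cells `P/H`, `P/P`);
* **Group 3** receives drug in one period and placebo in the other, told
  unknown both times (cells `H/U`, `P/U`).

Outcomes are symptom intensities (drowsiness, mouth-dryness, nausea,
itchiness) self-reported on a 100 mm visual analog scale (VAS) at baseline
and ten post-dose timepoints over 7 h, reduced to the trapezoidal
area under the curve (AUC, mm·hr). Under the reference trial's calibration
(25 mg hydroxyzine in healthy volunteers, NCT01501591), drowsiness is the
therapeutic outcome, mouth-dryness the adverse outcome, nausea a positive
control for the placebo effect (suggested to participants but not caused by
the drug), and itchiness a negative control with no effects at all.

## The additive interaction model

Writing $D$, $P$ and $I$ for the drug, placebo and interaction effects of
one outcome (on the adjusted AUC scale), the expected elevation of each cell
over the reference cell `P/P` is:

| cell | expectation |
|------|-------------|
| `P/P` | $0$ (non-specific passive changes only) |
| `H/P` | $D$ |
| `P/H` | $P$ |
| `H/H` | $D + P + I$ |
| `H/U` | $D + \lambda P + \lambda I$ |
| `P/U` | $\lambda P$ |

The *belief weight* $\lambda \in [0,1]$ is the fraction of the placebo (and
therefore interaction) effect realized when the assignment is disclosed as
unknown. The six estimable effects are cell contrasts:

* `total` $= H/H - P/P = D + P + I$
* `model_drug` $= H/P - P/P = D$
* `drug_plus_interaction` $= H/H - P/H = D + I$
* `conventional_drug` $= H/U - P/U = D + \lambda I$ — the RPCT estimate
* `placebo_1` $= H/H - H/P = P + I$
* `placebo_2` $= P/H - P/P = P$

so the interaction is identified as `placebo_1 − placebo_2`, the
conventional estimate overshoots the drug effect by $\lambda I$ when the
interaction is positive, and the departure of the total effect from
additivity, `total − (model_drug + placebo_2)`, equals $I$.

## The generative simulator

No subject-level data are deposited for the reference trial, so the package
ships a generative simulator whose defaults *are* the trial's conditions,
and against which the whole pipeline is validated.

For subject $i$, period $p$, outcome $o$ and grid time $t$:

$$y_{ipt} = \mu_o + u_i + \delta_o\,[p = 2]\,[t > 0]
  + D_o f_d(t)\,r + P_o f_p(t)\,b + I_o f_i(t)\,r b + \varepsilon_{ipt}$$

clamped to $[0, 100]$, with $r$ the received-drug indicator and $b$ the
belief factor ($1$, $0$, or $\lambda$). Components and defaults:

* **Effect sizes** are specified on the adjusted-AUC scale (mm·hr) and
  converted to per-timepoint magnitudes in mm by dividing by the profile
  AUC; a noiseless trial therefore reproduces them exactly through the
  estimation pipeline. Defaults equal the reference trial's adjusted
  estimates: drowsiness $D$/$P$/$I$ = 58.3/40.8/35.1, mouth-dryness
  9.5/25.3/23.8, nausea 0/7.5/12.4, itchiness 0/0/0 mm·hr. The trial
  reported an interaction on nausea despite a null drug effect (a
  cross-outcome interaction: the drug's drowsiness pharmacology modifying
  the nausea expectancy); `interaction_auc` is an ordinary per-outcome
  parameter, so this is representable directly.
* **Time profiles** (`time_profile()`): unit multipliers on the grid. The
  drug profile rises linearly to 1 at 2.5 h, is flat to 6 h, and declines
  to 0.5 at 7 h (sedation onset within the first hour, peak at 2–3 h,
  persistence about 6 h); its AUC is 5.5 hr. The placebo profile steps to 1
  at the first post-dose point and stays flat (expectancy responses start
  earlier and are flatter than the drug's time course); AUC 6.75 hr.
  The trial reports no functional forms; these are calibration choices and
  configurable. Whether the interaction tracks the drug or the placebo time
  course is likewise unreported; we default the interaction profile to the
  placebo profile, since the interaction is generated by the same belief
  mechanism.
* **Belief weight** $\lambda = 0.5$: under a 50/50 disclosure and an
  (observed) approximately linear relation between certainty and placebo
  response, told-unknown realizes half the effect. The conventional
  contrast is linear in $\lambda$ by construction, and
  `run_bias_experiment()` verifies the slope.
* **Period effect** $\delta_o$: applied as a uniform shift at post-dose
  timepoints only, calibrated on the AUC scale to the trial's adjusted
  period effects (25.3/16.2/6.7/3.4 mm·hr) through the step-profile factor
  6.75. Restricting $\delta$ to $t > 0$ keeps the baseline covariate free
  of the period effect, so the ANCOVA period coefficient recovers the
  full AUC-scale value; letting it shift the baseline too would split the
  effect between the covariate and the period term.
* **Variance components**: subject intercept $\sigma_{subj} = 8$ mm shared
  across periods, residual $\sigma_{\varepsilon} = 10$ mm per observation,
  baseline-specific residual SD per outcome (8/11/6/4.5 mm) near the
  trial's baseline SD table. These give simulated CI widths of the same
  order as the reported ones. Baseline means (5.0/6.3/2.9/2.8 mm) follow
  the trial's baseline table.
* **Carryover** is assumed absent: the 72-h washout spans several drug
  half-lives (about 20 h), and no carryover term is modeled.
* **Randomness**: a single master seed drives the schedule, subject
  intercepts, baselines, residuals and dropout, in that documented order.

### What the simulator does and does not emulate

Scores are clamped to the VAS range *after* noise. With baselines near
5 mm and residual SDs of 8–14 mm, the floor at 0 censors a substantial
share of reference-cell observations — as real VAS data are censored. Two
consequences matter for interpreting validation results:

1. **Attenuation.** Stochastic runs under default calibration recover
   contrasts somewhat below their analytic values (cells sitting near the
   floor lose more of an added effect than elevated cells); exact-identity
   tests therefore use noise-free parameters with baselines away from the
   bounds, where clamping is provably inert.
2. **Partial nulls.** With a drug effect present but $I = 0$, group 1's
   placebo contrast is measured further from the floor than group 2's, so
   censoring alone shifts `placebo_1 − placebo_2` upward. The type-I error
   of the interaction test is therefore evaluated on the design's own
   negative control (itchiness: $D = P = I = 0$), where censoring is
   symmetric across cells and the test attains its nominal level. This
   floor-induced distortion under partial nulls is a genuine property of
   bounded scales at low baselines, not of the z test; analyses of real
   low-baseline VAS outcomes inherit it.

The simulator also does not model informative dropout (dropout removes
period-2 data at random), learning or expectancy drift beyond the additive
period effect, or pharmacokinetics.

## Estimation

`fit_ancova()` fits the trial's ANCOVA: AUC on intercept, period-specific
baseline score, period, and condition — plus group and
subject-nested-within-group terms for the within-group scope. Decisions the
trial's description leaves open, resolved here:

* **Subject effects are fixed**, not random: the term list
  ("subject-nested within group") is reproduced as a fixed-effects ANCOVA
  rather than assuming an unstated mixed model. The within fit absorbs
  subjects by within-subject centering, which is algebraically the full
  dummy-variable fit (the tests verify this against an explicit
  normal-equations oracle to 1e-10, including SEs and residual df). With
  subject effects present, group is aliased and only the within-pair
  condition contrast is identifiable per group, so conditions are coded
  against a per-group reference cell (`H/P`, `P/P`, `P/U`).
* **Baseline covariate** is the period-specific t = 0 score. The AUC
  includes the baseline node as its first trapezoid point and is *not*
  baseline-subtracted — adjustment happens once, in the covariate.
* **Normal reference**: CIs are point ± 1.96·SE and comparisons use the z
  test with combined SE $\sqrt{SE_a^2 + SE_b^2}$, matching the trial's
  machinery; at n ≈ 160/group the difference from t is negligible.
* **No multiplicity adjustment** anywhere, matching the trial.
* Within-group effects come from different groups and are treated as
  independent in combined-SE comparisons; comparisons that share a cell
  (the additivity gap vs total) carry an `independent = FALSE` caveat flag
  since that covariance is ignored.
* The non-parametric secondary tests are not named by the trial; we use
  Wilcoxon signed-rank (within-group, paired period differences on
  unadjusted AUCs) and rank-sum (between-group), exact for n ≤ 25.

Derived metrics divide by estimated effects: the overestimation percentage,
`100·(conventional − model)/model`, is unstable when the model drug effect
is near zero (the itchiness negative control can produce large meaningless
percentages); percentages are stored unrounded and rounded only for
display.

## Numerical and degenerate-input choices

* Noise-free fits have zero residual variance; SEs are exactly 0 and
  z-based p-values degenerate to 0/1 — exact-identity tests compare points
  only. A zero combined SE with a nonzero difference yields an explicit
  infinite z with a warning.
* Constant covariates (e.g. the baseline at zero noise) are dropped as
  aliased; rank deficiency involving *condition* terms is an error naming
  the collinear terms, never a silent drop.
* Trapezoid AUC uses the exact grid; series with missing timepoints are an
  error, not interpolated. Subjects without a complete crossover are
  excluded and reported, mirroring the trial's exclusions.
* Blocks are permuted independently and uniformly from the seed (the trial
  used an external web generator, which is not reproducible); block sizes
  must be multiples of 6 so each block holds whole assignment sets.

## Validation problem sizes

The test suite validates exact identities on noise-free trials of 12 per
group, the normal-equations oracle on 8 per group, parameter recovery and
SE ordering at 40–160 per group, and the interaction test's type-I error
at the trial's own scale — 160 per group over 2,000 simulated trials.
Power/bias experiments in the examples use reduced replication; all are
reproducible from their seeds.

## A worked decomposition

```{r report}
report <- run_report(n_per_group = 160, dropout = 0.015, seed = 7)
report$metrics |> mutate(across(where(is.numeric), ~ round(.x, 1)))
```

The drowsiness row shows the design's signature: a positive interaction
(placebo effect-1 well above placebo effect-2), a conventional estimate
above the model-estimated drug effect, and a total effect exceeding the
drug + placebo sum by approximately the interaction.

## Known limitations

* Calibration equates analytic (unclamped) effects with the trial's
  adjusted estimates; stochastic recovery is attenuated by floor censoring
  at low-baseline outcomes (see above), so simulated estimates are
  conservative relative to the calibration targets.
* The subject intercept induces a common correlation across periods and
  outcomes; real placebo responsiveness may be outcome-specific, so the
  simulated cross-outcome placebo correlations are optimistic.
* Binary-scale outcomes are reduced by thresholding the simulated VAS at
  5 mm and analysed with the same linear contrast machinery (as counts),
  not a logistic model.
* The power experiment's rejection rates inherit the z test's slight
  liberality at small n; sample sizes below ~20/group are outside the
  intended regime.
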