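# bpcross

Drug\*placebo interaction analysis for hybrid balanced-placebo /
randomized placebo-controlled crossover trials.

## The problem

A randomized placebo-controlled trial (RPCT) estimates a drug effect as
medication arm minus placebo arm, implicitly assuming the drug effect and
the placebo effect (the meaning response to believing one received an
active drug) are additive. If they interact, the interaction occurs only in
the medication arm and the conventional estimate is biased. The balanced
placebo design crosses what participants *receive* (drug `H` / placebo `P`)
with what they are *told* (`H` / `P`); the hybrid design adds the RPCT
cells (told unknown, `U`) so conventional and model-based drug estimates
can be compared head-to-head in one trial of three crossover arms.

`bpcross` is for trial statisticians and methodologists who want to design,
simulate, or analyse such trials: it provides the block-randomization
schedule, a calibrated generative simulator of VAS symptom time courses, AUC
outcome reduction, the ANCOVA contrast estimation, combined-SE effect
comparisons, derived bias metrics, and Monte Carlo power experiments.

## The model

With drug effect $D$, placebo effect $P$, interaction $I$ (adjusted AUC
scale, mm·hr) and belief weight $\lambda$ (fraction of the placebo effect
realized when told "unknown"; 0.5 under a 50/50 disclosure), cell
expectations over the reference cell `P/P` are

    H/P = D        P/H = P          H/H = D + P + I
    H/U = D + λP + λI               P/U = λP

giving the six effects as condition contrasts, estimated by ANCOVA
(baseline, period, condition, plus group and subject-within-group for the
within-group contrasts):

| effect | contrast | estimates |
|---|---|---|
| `total` | H/H − P/P | D + P + I |
| `model_drug` | H/P − P/P | D |
| `drug_plus_interaction` | H/H − P/H | D + I |
| `conventional_drug` | H/U − P/U | D + λI (the biased RPCT estimate) |
| `placebo_1` | H/H − H/P | P + I |
| `placebo_2` | P/H − P/P | P |

The interaction is `placebo_1 − placebo_2`, tested by a z test with
combined SE `sqrt(se₁² + se₂²)`. Defaults throughout are calibrated to a
randomized crossover trial of 25 mg hydroxyzine in healthy volunteers
(NCT01501591); see `hydroxyzine_trial_estimates()` and the methods
vignette (`vignettes/balanced-placebo-decomposition.Rmd`).

## Worked example

```r
library(bpcross)
library(dplyr)

report <- run_report(n_per_group = 160, dropout = 0.015, seed = 7)
report$metrics |> mutate(across(where(is.numeric), ~ round(.x, 1)))
#> # A tibble: 4 × 7
#>   outcome       interaction total additivity_gap effect_sum overestimation_pct
#>   <chr>               <dbl> <dbl>          <dbl>      <dbl>              <dbl>
#> 1 drowsiness           42.3 119.            41.2       77.5               46.3
#> 2 itchiness            -2    -2.1           -3.5        1.4            -1072.
#> 3 mouth_dryness        19.1  48.4           20         28.4              148.
#> 4 nausea               11.9  15.4           11.9        3.6              534.
```

One simulated trial at the planned size (160/group, ~1.5% dropout). For
drowsiness: the estimated drug\*placebo interaction is 42.3 mm·hr (placebo
effect-1 minus placebo effect-2), the total effect (119 mm·hr) exceeds the
drug + placebo sum by 41.2 mm·hr (the additivity gap, which estimates the
same interaction), and the conventional RPCT drug estimate overshoots the
model-estimated drug effect by 46%. Itchiness is the built-in negative
control — its interaction is a null −2 mm·hr, and its overestimation
percentage is meaningless (near-zero denominator), which is why ratio
metrics should only be read for outcomes with a real drug effect.
`report$effects` holds the six effect estimates per outcome with CIs and
p-values; `print(report)` gives a full narrative block per outcome.

Other entry points: `simulate_trial()` / `reduce_trial()` /
`estimate_all()` for the pipeline pieces, `nonparametric_effect()` and
`placebo_correlations()` for secondary analyses, `sample_size()`,
`run_power_experiment()` and `run_bias_experiment()` for design questions,
and a thin CLI (`inst/cli/bpcross.R`) with subcommands
`simulate | reduce | estimate | report | power`.

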