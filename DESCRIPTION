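Package: bpcross
Title: Drug*Placebo Interaction Analysis for Balanced-Placebo Crossover Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing hybrid
    balanced-placebo / randomized placebo-controlled crossover trials in which
    what a participant receives (drug or placebo) is crossed with what they
    are told they receive (drug, placebo, or unknown). Provides a
    block-randomization schedule generator, a generative simulator of
    visual-analog-scale symptom time courses under an additive
    drug + placebo + drug*placebo-interaction model, trapezoidal
    area-under-the-curve outcome reduction, ANCOVA-based estimation of the six
    effect contrasts the design identifies (total, model-estimated drug,
    drug + interaction, conventional drug, and two placebo effects),
    combined-standard-error z comparisons between effects, derived bias
    metrics (overestimation of the conventional drug effect, interaction
    share of the total effect), non-parametric secondary tests, and Monte
    Carlo power and bias experiments, calibrated by default to a randomized
    hydroxyzine trial (NCT01501591).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
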