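Package: stressmet
Title: Multi-Environment Trial Analysis of Abiotic Stress Tolerance Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying stress-tolerant crop ideotypes from
    balanced multi-environment trials. Raw replicate-level trait values
    observed under optimal, drought and heat conditions are converted into
    per-season tolerance index environments; these are analysed by joint
    ANOVA with variance components and quantitative-genetic parameters,
    AMMI (additive main effects and multiplicative interaction)
    decomposition with Gollob tests, BLUP-based WAASB/WAASBY stability
    indexing, multi-trait genotype-ideotype distance (MGIDI) selection
    with factor analysis, stepwise multiple linear regression for trait
    contribution, and Ward clustering with linear discriminant validation.
    A seeded synthetic trial generator with known genotype, interaction
    and tolerance-group structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
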