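Package: envherit
Title: Environment-Specific Heritability and Evolvability from Half-Sib Breeding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of traits expressed across
    discrete developmental environments using a half-sib split-brood breeding
    design. Builds the additive genetic relationship matrix from a pedigree,
    fits a character-state animal model by restricted maximum likelihood
    (EM warm start followed by average-information updates) with an
    unstructured genetic covariance matrix across environments, and converts
    the fitted variance components into per-environment heritability (with
    delta-method standard errors), coefficients of additive genetic variation,
    and mean-standardized evolvability. Also includes a simulator for half-sib
    split-brood datasets with known genetic architecture, and the
    trait-expression stage of the analysis: log-scale one-way ANOVAs with
    Tukey-Kramer comparisons and allometric ANCOVAs with an
    interaction-screening rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
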