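Package: sciuromorph
Title: Craniodental Ecomorphometrics for Hybridizing Pine Squirrels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for craniodental ecomorphology of pine
    squirrels (Tamiasciurus) across a hybrid zone: incisor-based bite-force
    quotients, cranial-suture complexity length ratios, landmark and
    semilandmark geometric morphometrics of the mandible (generalized
    Procrustes analysis, bending-energy sliding of semilandmarks, principal
    component analysis with Monte Carlo axis tests, Procrustes ANOVA by
    residual-randomization permutation), Bayesian multivariate-normal
    morphospace-overlap probabilities, and admixture-trait regressions.
    Includes a synthetic-data generator with known ground truth for testing
    and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
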