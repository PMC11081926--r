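Package: socialforage
Title: Simulation and Evidence-Accumulation Modelling of Decisions to Leave
    Social Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying when people leave social interactions as a
    patch-leaving problem. Provides a generator for a virtual dictator-game
    task in which partners share exponentially decaying proportions of
    varying stakes inside social environments of different average
    generosity or travel effort; three drift-diffusion models of leaving
    times driven by fairness, scaled reward, or nothing; maximum-likelihood
    grid-search fitting of those models via a two-sample Kolmogorov-Smirnov
    likelihood with BIC model comparison and recovery studies; a synthetic
    cohort generator with heterogeneous parameters and depression and
    loneliness covariates; and the mixed-effects analysis stage (effect
    coding, Type II Wald tests, simple effects) applied to leaving times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    car,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
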