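Package: frsex
Title: Sex-Comparative Functional Response Analysis for Predator-Prey
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Rogers Type II random-predator (prey-depletion) model
    to foraging-trial data by maximum likelihood, using the Lambert W
    closed-form solution of the implicit consumption equation.  Provides
    response-type determination by logistic regression, small-sample AICc
    model comparison against a Type I alternative, nonparametric stratified
    bootstrapping of attack rate and handling time with percentile
    confidence intervals, between-group contrasts (consumption at a fixed
    prey density, maximum consumption rate, functional response ratio),
    binomial-logit models of the proportion of prey consumed against prey
    density, consumer sex and claw or carapace morphology, and a
    population-level sex-ratio sweep that quantifies how far an all-male
    sample overestimates the consumption efficiency of a mixed-sex
    population.  Includes synthetic-data generators for foraging trials,
    morphology surveys, movement tracks and trapping records so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
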