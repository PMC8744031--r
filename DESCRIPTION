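Package: lifeineq
Title: Normalized Lifespan Inequality Indices for Life Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring inequality in length of life from period
    life tables. Implements the classical lifespan-inequality indices
    (absolute and relative Gini, standard deviation, coefficient of
    variation, e-dagger, life-table entropy) on age-at-death
    distributions, together with normalized versions that compare
    observed inequality with the maximal inequality attainable given the
    distribution's mean and a finite maximal lifespan. Includes the
    two-point maximal-inequality benchmark, robustness analysis of
    pairwise comparisons with respect to the assumed maximal lifespan,
    age decomposition of inequality change by the continuous-change
    (Horiuchi) method, panel analytics for the longevity-inequality
    relationship, a reader and writer for the Human Mortality Database
    period 1x1 life-table text format, and a Siler-model generator of
    synthetic life-table panels emulating the epidemiological transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
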