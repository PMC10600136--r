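Package: froptn
Title: Fixed-Reference Ordinal Partition Transition Networks for Hemoglobin Time Series
Version: 0.1.0
Authors@R:
    person("froptn", "maintainers", email = "froptn@example.org", role = c("aut", "cre"))
Description: Maps multivariate hemoglobin time series (oxy-, deoxy-, total
    hemoglobin, oxygen exchange and oxygen saturation) onto a ten-state
    fixed-reference ordinal partition, derives the 100-type synchronous
    transition matrix of the implied Markov chain, and computes the full
    suite of adjacency-matrix coefficients: transition probabilities,
    pre/post-transition dwell times, component means and fluxes, under
    grand-average and alternative averaging schemes.  Provides higher-order
    co-dependence analyses across coefficient matrices (conic-section and
    hyperbola fitting by a generalized-eigenvector method, transition-class
    trends, sign-reversal tables, contralateral t-prime normalization,
    flux-vector amplitudes, Lineweaver-Burk double-reciprocal regressions
    and biomarker-group comparisons), a synthetic-data generator with
    geometric null models and surrogate series, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
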