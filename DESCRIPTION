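Package: osrr
Title: Over-Shrinkage Ridge Regression for Network-Adjusted Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a global gene co-expression network from a large
    training ("database") expression matrix by heavily penalized per-gene
    ridge regression with self-exclusion, and uses the network prediction of
    each gene, rescaled by a per-gene least-squares coefficient, as a
    covariate in small-sample analyses: network-adjusted differential
    expression, network-disruption (interaction) tests, and cosinor models of
    rhythmic expression. Includes beta-uniform mixture modelling of p-value
    histograms, permutation-based null calibration, synthetic-data generators
    with ground-truth bookkeeping for power and type-I-error evaluation, and
    a command-line front end for file-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
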