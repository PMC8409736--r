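Package: gpgrowth
Title: Gaussian Process Analysis of Microbial Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric analysis of microbial growth assays with Gaussian
    process (GP) regression. Reads multiwell plate-reader time series and
    well metadata, applies an ordered preprocessing pipeline (blank and
    control subtraction, positivity enforcement, natural-log transform,
    baseline anchoring), fits radial-basis-function GP models to single or
    pooled replicate curves, and infers growth parameters (carrying
    capacity, maximum specific growth rate, lag and adaptation time, area
    under the curve, doubling time, death and maximum death rate) with
    uncertainty from the posterior. Detects multiphasic (diauxic) growth
    from derivative posteriors, and tests for differential growth between
    conditions with log Bayes factors, permutation-based false discovery
    thresholds, and functional-difference summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
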