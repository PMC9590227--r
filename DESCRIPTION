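Package: methrel
Title: Reliability of DNA Methylation Predictors Across Preprocessing Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A replicate-based evaluation framework for DNA-methylation
    predictors on Infinium-style arrays. Simulates methylated/unmethylated
    intensity data with controlled technical artifacts (background, dye bias,
    probe-type compression, batch effects), processes it through a composable
    grid of preprocessing kernels (out-of-band or negative-control background
    correction, mean or regression-based dye-bias correction, stratified
    quantile normalization, probe-type calibration), computes weighted-CpG
    predictor estimates such as epigenetic clocks, quantifies technical
    consistency via the intraclass correlation family on technical replicate
    pairs, decomposes batch-effect variance, and measures how pipeline choice
    propagates to downstream phenotype associations including Cox mortality
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    survival,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
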