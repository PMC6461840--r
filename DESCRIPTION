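Package: ecmsom
Title: Nutritional-Phase Chemistry, Spectral Unmixing and Transcriptional
    Response Types for Ectomycorrhizal Decomposition Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for liquid-culture assays in which
    ectomycorrhizal fungi decompose a soil-organic-matter (SOM) extract
    while consuming glucose and ammonium.  Detects the four nutritional
    phases (active growth, ammonium depletion, carbon depletion, prolonged
    carbon depletion) from culture chemistry, unmixes infrared spectral
    time series by multivariate curve resolution with alternating
    non-negative least squares, estimates iron redox state from Fe K-edge
    pre-edge centroids, ordinates nitrogen K-edge speciation tables,
    computes the Ox/C3-G lignin side-chain oxidation marker, calls
    differentially expressed genes with a simplified negative-binomial
    stage, and classifies genes into qualitative transcriptional response
    types whose enrichment in SOM-interaction annotations is assessed by a
    time-point permutation test.  A synthetic-data module generates every
    input with the statistical structure the analysis assumes, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
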