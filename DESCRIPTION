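Package: colonyhet
Title: Colony-Level Quantification of Phenotypic Heterogeneity in
    Fluorescence Reporter Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phenotypic heterogeneity of bacterial
    colonies carrying a fluorescent expression reporter.  Provides a seeded
    synthetic plate-image generator with ground-truth sidecars, an automatic
    colony-detection pipeline (thresholding, size/shape filtering, circle
    fitting, sector scoring, manual curation), mixture-model classification
    of colonies into reporter-positive and reporter-negative classes,
    dose-response and switching-rate curve fits with parameter standard
    errors, Mann-Whitney rank comparisons, flow-cytometry event gating and
    colony generation-number estimates, plus a command-line interface for
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
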