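Package: pneumaticity
Title: Quantifying Skeletal Pneumaticity from MicroCT Volumetrics with
    Phylogenetic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying postcranial skeletal pneumaticity in birds
    from microCT-derived tissue volumes. Segments grey-value voxel grids into
    air, marrow and bone by thresholding, converts voxel counts to physical
    volumes, and computes air space proportions (ASP) and bulk bone density
    under standard tissue-density assumptions. Comparative analyses use
    phylogenetic generalized least squares with Pagel's lambda estimated by
    maximum likelihood, AICc-based model selection with Akaike weights, and a
    residual-based bone thickness index (BTI). Includes a synthetic-data
    generator (digital bone phantoms with analytically known volumes, Yule
    trees, and trait tables with known generative parameters) so the whole
    pipeline is testable without scan data, plus a config-driven pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
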