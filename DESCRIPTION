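Package: trnadapt
Title: Transcriptional Regulatory Network Adaptation Analysis for
    Regulator Knockout Evolution Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcription-factor knockout adaptive
    laboratory evolution studies. Rescales independent-component-analysis
    regulatory-module (iModulon) activities onto a basal-activity scale
    where zero means no regulatory activity, scores and selects regulators
    for knockout, computes directed regulatory-network statistics
    (reachability, betweenness, node-removal impact, regulon subnetwork
    skewness), converts kinetic phenotyping-plate opacity readings into
    binary growth calls with family-wise error control, detects convergent
    mutations across independent evolution lineages, and classifies each
    knockout strain into four adaptation categories. A synthetic-data
    module generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
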