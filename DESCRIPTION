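Package: pbinet
Title: Paired Biomarker Scoring and Metabolite Ratio Networks for
    Longitudinal Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes metabolites from paired (longitudinal or
    cross-over) concentration data with the paired Biomarker Identifier
    (pBI) score, a signed signal-to-noise statistic built from
    per-subject fold changes, and infers metabolite interaction networks
    by scoring absolute log2 concentration ratios of analyte pairs and
    thresholding the scores. Includes kinetic (per-timepoint) networks,
    hub and degree summaries, threshold selection by cross-validated
    k-nearest-neighbor accuracy on network-selected features, a
    correlation-network comparison baseline, a synthetic longitudinal
    cohort generator with planted responder metabolites for validation,
    and a command-line interface with GraphML/SIF/edge-list exports
    loadable by Cytoscape.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    graphics,
    grDevices,
    igraph,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
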