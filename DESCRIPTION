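Package: mechmap
Title: Mechanistic Disease-Map Modeling and Explainable Drug-Target Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds mechanistic disease maps from gene and phenotype
    annotations mapped onto signed signaling-pathway graphs, estimates
    per-sample circuit activities by recursive signal propagation, learns
    circuit activities from known-drug-target expression with multi-output
    tree ensembles explained by TreeSHAP attributions, and prioritizes
    targets and repurposable drugs via stability-validated selection,
    hierarchical clustering with the gap statistic, drug-category
    over-representation, and effect-reversal filtering. Ships a seeded
    synthetic-data generator with planted causal structure so the whole
    workflow is testable end to end, exercised on a retinitis pigmentosa
    disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xgboost,
    edgeR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
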