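Package: qhtsER
Title: Quantitative High-Throughput Screening Analysis for Estrogen
    Receptor Agonist and Antagonist Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses plate-based quantitative high-throughput
    screens (qHTS) of nuclear-receptor reporter-gene assays run in agonist and
    antagonist mode with multiplexed cell-viability and autofluorescence
    counter-screens. Provides a synthetic screen generator with ground-truth
    pharmacology, control-based plate normalization and quality control
    (signal-to-background, CV, Z'-factor, embedded control titrations),
    bounded four-parameter Hill curve fitting with categorical curve
    classification, a decision tree assigning per-compound activity outcomes
    with cytotoxicity and autofluorescence demotion, replicate and duplicate
    reconciliation, evaluation against reference-chemical and binding-assay
    labels (sensitivity, specificity, concordance, Fisher exact tests), and
    self-organizing-map clustering of structural fingerprints with
    cluster-level activity enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
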