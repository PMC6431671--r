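Package: itraqnet
Title: Integrative iTRAQ Proteomics and Network Pharmacology Target Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for integrative pharmacology studies that
    combine quantitative serum proteomics with network-based target
    prediction. Implements iTRAQ 4-plex reporter-ion quantification
    (isotope-overlap correction, peptide-to-protein rollup, per-batch
    normalization) and differential-protein calling under fold-change,
    significance, peptide-count, score and patient-consensus filters;
    Tanimoto fingerprint screening of candidate compounds; construction of
    typed herb-compound-target-disease networks with combined-score edge
    filtering; degree/betweenness/closeness hub screening by the
    triple-median rule; hypergeometric pathway overrepresentation with fold
    enrichment; and an integration step that merges predicted hubs with
    experimental differential proteins and nominates key therapeutic
    targets. A seeded synthetic-data generator with planted ground truth
    replaces study-specific raw data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
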