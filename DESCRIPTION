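Package: kipquant
Title: Kinase Inhibitor Pulldown PRM Quantification and Kinome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and downstream statistics for kinase inhibitor
    pulldown (KiP) targeted proteomics. Provides transition-level parallel
    reaction monitoring (PRM) quantification with automatic peak-boundary
    detection, fragment-concordance filtering and top-6 summation; rule-based
    PRM peptide panel design with dilution response-curve evaluation; a
    deterministic simulator of internal-standard-triggered (IS-PRM) acquisition
    with total-ion-current normalization; enrichment linearity and serial
    depletion metrics including iBAQ totals over in-silico tryptic digests; and
    subtype differential-kinome statistics (per-gene t-tests with
    Benjamini-Hochberg correction, hierarchical and k-means clustering,
    cross-dataset correlation). Seeded synthetic-data generators with planted
    ground truth emulate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
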