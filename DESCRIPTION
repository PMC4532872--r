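Package: triocnv
Title: Trio-Based CNV Consensus Calling, Rare-Variant Filtering and Clinical Tiering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for prioritizing copy number variants (CNVs) in
    parent-child trios genotyped on SNP arrays. Merges per-sample call sets
    from multiple CNV-calling algorithms into consensus events under
    autosome and chromosome-X evidence rules, filters them to rare variants
    against population control cohorts by reciprocal overlap, classifies
    each surviving child variant as de novo or inherited, assigns a clinical
    tier from explicit size, gene-content and known-locus rules, and reports
    cohort-level statistics including a Fisher exact test of motor-severity
    association. Ships a seeded synthetic cohort generator with a
    ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
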