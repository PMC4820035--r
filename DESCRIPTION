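Package: cnvenrich
Title: Rare Copy-Number-Variant Gene-Set Enrichment for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools rare copy-number variants (CNVs) from multi-study
    case-control cohorts, applies the standard rare-CNV quality filters
    (size threshold, population frequency, overlap with common-CNV and
    segmental-duplication masks), annotates CNVs onto gene footprints, and
    tests gene sets for an excess of case CNV hits with a nested
    logistic-regression deviance (likelihood-ratio) test that adjusts for
    study of origin, CNV length and the number of genes hit outside the
    set. Supports deletion/duplication stratification, duplication-versus-
    deletion differential tests, gene-wise scans, leave-one-study-out
    sensitivity analyses, and a hypothesis-free pathway screen corrected
    with Storey q-values. Includes seeded simulators for regression-level
    calibration studies and full genomic multi-study cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
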