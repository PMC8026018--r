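Package: fibropath
Title: Cross-Disease Fibrosis Pathway Analysis and Drug Repurposing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cross-disease transcriptomics
    pipeline for fibrotic diseases: differential-expression signature
    extraction with microarray and RNA-Seq filtering rules, gene-map-guided
    random walks on a shared-gene pathway network with odds-ratio and
    chi-square significance assessment, signature-inversion drug candidate
    filtering and per-cluster re-ranking, Tanimoto fingerprint screening
    against drugs that failed in clinical trials, and hypergeometric tests
    for cross-disease drug-candidate overlap. A synthetic-data module
    generates every required input with known planted truth (differentially
    expressed genes, enriched pathways, structural drug clusters) so the
    full pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    edgeR,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
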