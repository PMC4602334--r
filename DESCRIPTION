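Package: NotIPanel
Title: Marker Panels and Network Enrichment from NotI-Microarray
    Aberration Calls
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of NotI-microarray methylation/deletion
    calls from tumor cohorts. Provides a SummarizedExperiment-based
    container for sample-by-locus aberration calls, per-group frequency
    tables and clone filters, exact two-group contingency testing,
    count-threshold marker-panel classification with lift-curve and Gini
    interval evaluation, exhaustive panel search, and link-counting
    network enrichment analysis against functional-coupling networks and
    gene-set collections. A synthetic-cohort generator emulating a
    prostate-tumor study design (15 adenomas, 14 nonaggressive and 4
    aggressive carcinomas over 180 chromosome-3 loci) exercises every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: DNAMethylation, Classification, NetworkEnrichment,
    CopyNumberVariation, Epigenetics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
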