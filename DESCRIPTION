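Package: gamforge
Title: Genome Architecture Mapping Analysis from Segregation Tables to Chromatin Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Genome Architecture Mapping (GAM) data:
    window calling from nucleotide coverage with orphan-window minimisation,
    sample quality control, co-segregation and normalized pointwise mutual
    information (NPMI) contact matrices, distance-stratified Z-score
    normalization, differential contact detection, multiscale insulation
    scores and TAD boundary calling, A/B compartment assignment from
    observed/expected correlation matrices, a Kolmogorov-Smirnov domain
    melting score for long genes, trans-cis contact ratios, transcription
    factor feature-pair scoring on differential contacts, and an in-silico
    GAM simulator (polymer ensembles, nuclear slab slicing, nuclear-profile
    pooling) used to validate every stage from synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
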