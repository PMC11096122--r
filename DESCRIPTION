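Package: mitodlp
Title: Single-Cell mtDNA Copy Number, Heteroplasmy and Clonal Inference
    for Amplification-Free scWGS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of mitochondrial and nuclear genomes from
    amplification-free single-cell whole-genome sequencing. Estimates
    per-cell mtDNA copy number and the mtDNA-to-nuDNA ratio (MNR) from
    depth ratios calibrated to nuclear ploidy, genotypes heteroplasmic
    mtDNA variants through a strand-aware filter stack, assigns cells to
    clones with a binomial-mixture model (MityBayes) fit by EM or
    gradient MAP optimization with an exact enumeration oracle, and
    tests heteroplasmy-to-copy-number association with a stratified,
    library-weighted concordance statistic. Ships a synthetic single-cell
    data generator so the full pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
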