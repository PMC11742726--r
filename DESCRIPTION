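Package: pmlfilter
Title: Host Read Filtration and Re-Identification Auditing for Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes host (human) reads from metagenomic sequencing data
    using per-read pseudo-matching-length (PML) profiles computed against a
    pangenome reference index. Provides exact matching-statistics indexing
    over arbitrary reference sets, maximum/average/custom PML score metrics
    with calibrated classification thresholds, composable alignment- and
    index-based filtration pipelines with paired-end bookkeeping, a labeled
    synthetic human/microbial read-mixture benchmark, a coverage
    depth/breadth artifact diagnostic, and a genotype-likelihood
    re-identification audit that quantifies residual patient-identifying
    signal in the reads that survive filtration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
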