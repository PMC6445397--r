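Package: methdelta
Title: Intra-Individual Differential Methylation Analysis for Paired RRBS
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of paired-timepoint reduced representation bisulfite
    sequencing (RRBS) experiments in which each individual is sampled twice,
    before and after an exposure. Implements per-individual differential
    methylation site calling with exact count tests and false discovery rate
    control, coalescing of shared sites into differentially methylated
    regions, assembly of region-by-sample methylation matrices, the
    intra-individual delta-methylation statistic log2(P10/P2), cohort batch
    correction, principal component and k-means decomposition with
    loading-threshold region selection, positional gene association with
    hypergeometric gene-set enrichment, and a beta-binomial simulator of
    paired RRBS experiments with ground-truth effect labels for recovery
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr
Config/testthat/edition: 3
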