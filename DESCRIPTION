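Package: exermeta
Title: Random-Effects Meta-Analysis of Exercise and Inactivity Muscle
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-wise random-effects meta-analysis of multi-study skeletal
    muscle transcriptomic responses to exercise and inactivity.  Provides
    within-study differential expression for paired and unpaired designs,
    restricted maximum-likelihood (REML) pooling of per-gene log2
    fold-changes with DerSimonian-Laird fallback and heterogeneity
    statistics, cross-study concordance analyses (missingness filtering,
    nearest-neighbour fold-change imputation, correlation and principal
    component analysis), significance-set logic with hypergeometric
    over-representation and protein-complex projections, per-gene forest
    interrogation with subgroup filters, and a multi-study paired-design
    transcriptome simulator with truth-recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    DESeq2
Config/testthat/edition: 3
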