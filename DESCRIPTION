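Package: conselem
Title: Sequence-Conserved Enhancer-Like Elements and Trait-Associated
    Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies enhancer-like elements from H3K27ac and chromatin
    accessibility peak calls, classifies their cross-species sequence
    conservation against gapless alignment blocks, and builds per-SNP
    binary annotations from the resulting element sets. Downstream, it
    estimates stratified heritability enrichment from GWAS summary
    statistics with block-jackknife standard errors, pools estimates by
    random-effects meta-analysis, quantifies overlap between fine-mapped
    variants and annotations with exact binomial tests, and prioritizes
    trait-associated elements with an annotation-informed spike-and-slab
    variational Bayes model on GWAS summary statistics and reference LD.
    Synthetic-data generators produce peaks, alignment blocks,
    block-structured genotypes, SNP effects, summary statistics, and
    fine-mapping tables so the whole pipeline can be exercised and
    validated by simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    metafor,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
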