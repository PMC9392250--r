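Package: wssgblup
Title: Weighted Single-Step Genomic BLUP and SNP-Window Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) for repeatability animal models
    and the iteratively weighted single-step GWAS (WssGWAS) that backsolves SNP
    effects from genomic breeding values, reweights marker variances, and scans
    10-SNP windows for the fraction of additive genetic variance they explain.
    Includes pedigree/genomic relationship matrices (A, A22, G, H-inverse),
    AI-REML variance component estimation with EM fallback, genotype quality
    control (call rate, MAF, exact Hardy-Weinberg test), gene-dropping
    simulation of pedigrees, genotypes and repeated phenotypes, candidate-gene
    annotation of significant regions, and intersection with differential
    expression results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
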