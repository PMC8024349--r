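Package: milkqtl
Title: Quantitative-Genetic Dissection of Test-Day Milk Traits: From Variance
    Components and Mixed-Linear-Model GWAS to Regulatory Variant Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the post-genotyping analysis chain used in
    dairy-cattle quantitative genetics: bivariate repeatability animal-model
    REML for heritabilities and genetic correlations on repeated test-day
    records, yield-deviation phenotypes, mixed-linear-model association scans
    against imputed sequence dosages with a genomic relationship matrix,
    QTL delineation (Bonferroni thresholding, 2-Mbp clustering, peak-based
    confidence intervals, conditional analysis), variant-consequence
    annotation against gene models, position-weight-matrix scoring of
    regulatory-SNP candidates, tissue-specificity scoring from an expression
    atlas, and two-locus genotype-interaction tests. A synthetic-data
    generator with known ground truth (pedigree, LD-structured dosages,
    test-day phenotypes with planted QTL, gene models, PWMs, expression
    atlas) drives recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    lme4,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
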