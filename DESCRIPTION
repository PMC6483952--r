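Package: haploblup
Title: Haplotype-Based Genomic Prediction with Random Haplotype Effects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction of dairy cattle breeding values from
    high-frequency marker haplotypes. Implements SNP quality control
    (call rate, minor allele frequency), construction of haplotype blocks
    from pairwise linkage disequilibrium (two-locus EM r2), multi-locus EM
    haplotype phasing with diplotype posteriors, deregression of estimated
    breeding values, four variants of a linear model with random haplotype
    effects solved through the mixed model equations, and generational
    cross-validation scored by Pearson correlation and the regression of
    EBV on DGV. A synthetic population generator with known haplotype
    effects supports testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
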