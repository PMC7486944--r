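Package: sgewas
Title: Social Genetic Effects Models and Single-Step GWAS for Group-Housed
    Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits an extended animal model for traits affected by social
    (indirect) genetic effects in group-housed animals, using Gibbs sampling
    over a single-step relationship matrix that combines pedigree and SNP
    information.  Derives total heritable variance and total heritability,
    back-solves SNP effects from genomic breeding values with iterative
    marker re-weighting, and decomposes additive genetic variance into 1-Mb
    map windows for QTL calling, separately for the direct and social
    genetic effect vectors.  Includes a synthetic-data generator (pedigree,
    groups, genotypes, phenotypes) under the same generative model, genotype
    quality control, and plain-text readers and writers for pedigree,
    phenotype, and PLINK-style genotype files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    graphics,
    grDevices,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
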