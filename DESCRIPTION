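Package: ssgwasr
Title: Single-Step Genomic BLUP and GWAS for Livestock Herd Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-step genomic evaluation and association analysis
    of growth and carcass traits in livestock. Builds pedigree (A) and genomic
    (G) relationship matrices with blending and tuning, assembles and solves
    the single-step mixed-model equations, estimates variance components by
    average-information REML (uni- and bivariate) with Monte-Carlo standard
    errors, back-solves genomic breeding values into per-SNP allele
    substitution effects with prediction-error variances and p-values,
    computes effective-test significance thresholds and inflation diagnostics,
    and maps significant SNPs to genes with hypergeometric set enrichment.
    Includes a synthetic herd simulator (pedigree, LD-structured genotypes,
    polygenic and QTL phenotypes, weight-age series) so the whole pipeline is
    testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
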