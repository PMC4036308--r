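Package: lactpath
Title: Pathway-Based GWAS Enrichment and Variance Partitioning for
    Milk Production Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether SNPs near the genes of a
    biological pathway are enriched for association with quantitative
    traits in pedigreed livestock populations.  Implements windowed
    gene-to-SNP assignment, weighted single-SNP linear mixed models
    with a pedigree polygenic effect (spectral REML), a permutation
    test of the proportion of significant pathway SNPs (PropSig)
    against random gene sets of matched size, and partitioning of
    genetic variance captured by pathway SNP sets relative to random
    near-gene SNP baselines using VanRaden genomic relationship
    matrices.  Includes a synthetic-data generator emulating a
    two-breed dairy-cattle study design (bull daughter-trait-deviation
    and cow repeated-lactation phenotypes) so the full analysis is
    testable without external data, plus transcriptions of three
    curated lactation gene sets (mammary development, prolactin
    signalling, involution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
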