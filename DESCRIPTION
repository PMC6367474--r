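Package: ighap
Type: Package
Title: Bayesian Haplotype and Gene Deletion Inference for Immunoglobulin
    Heavy Chain Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers immunoglobulin heavy chain (IGH) germline haplotypes,
    gene deletions and copy-number polymorphisms from AIRR-seq rearrangement
    tables. A heterozygous anchor gene (typically IGHJ6) labels the two
    chromosomes; each gene's alleles are assigned to chromosomes with a
    Bayes-factor model selection over binomial linkage counts. Includes a
    cohort-level binomial test for two-chromosome deletions, sequential
    posterior pooling across multiple heterozygous V anchors for D-gene
    deletion calling, allele usage bias sign tests, usage-threshold
    estimation for single-chromosome deletions, Jaccard comparison of
    haplotypes, and a diploid-repertoire simulator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
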