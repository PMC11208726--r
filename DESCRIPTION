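Package: haploae
Title: Linkage-Disequilibrium Aware Genotype Compression with Per-Block
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compresses dense SNP genotype panels while preserving local,
    potentially non-linear allelic structure. Chromosomes are partitioned
    into haplotype blocks with the confidence-interval (Gabriel/Haploview)
    criterion computed from two-locus EM haplotype frequency estimates, and
    each block is compressed with a standardized, formula-parametrized
    autoencoder whose width profile, depth and bottleneck follow a small
    set of hyperparameters. A matched-dimension PCA baseline, per-block and
    chromosome-wide reconstruction metrics, a founder-haplotype genotype
    simulator, and grid-search/elbow model-selection utilities support
    end-to-end evaluation on synthetic or user-supplied data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
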