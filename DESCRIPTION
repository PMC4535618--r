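Package: sweepherd
Title: Selective-Sweep Scanning and Population-Genomic QC for Multi-Breed
    Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of multi-breed whole-genome resequencing
    cohorts: a pooled-heterozygosity (Hp/ZHp) sliding-window selective-sweep
    scan from per-sample allele depths, functional SNP annotation into twelve
    effect categories with SIFT damaging/tolerant classification and
    breed-specific non-synonymous SNP extraction, transition/transversion and
    novelty quality control, genotype-similarity and Kimura two-parameter
    neighbour-joining population structure, and chip-versus-sequencing
    genotype concordance. Includes a fully specified multi-breed cohort
    simulator (Balding-Nichols breed differentiation, Hardy-Weinberg
    genotypes, Poisson read depth, embedded sweeps, chip error injection) so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
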