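Package: cosortpop
Title: Population Genomics of Co-Sorted Symbiont Single Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fine-scale genomic diversity in single
    amplified genomes (SAGs) of host-attached microbial symbionts, built
    around co-sorted symbiont/host cell pairs. Implements the full analysis
    chain: alignment filtering (identity, read quality, mapping quality),
    quality-aware pileups, per-site depth downsampling, minor-allele-frequency
    SNP calling, within-SAG SNP density and a read-pooling simulation that
    calibrates the signal expected from multiple distinct attached cells,
    multi-SAG consensus SNP calling with pN/pS over fourfold/onefold
    degenerate sites, per-gene and per-functional-category diversification
    statistics (ANOVA with Tukey HSD, chi-square over protein regions), and a
    multi-evidence (16S identity, ANI, phylogeny) species-clade delineation
    rule. A synthetic-data module generates annotated genomes, haplotype
    populations with controlled selection signatures, and MDA-biased SAG read
    sets with ground truth, so every statistic can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
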