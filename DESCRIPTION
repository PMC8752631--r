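Package: sweepscan
Title: Selective Sweep Detection for Recently Domesticated, Clonally Propagated Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic toolkit for detecting signatures of artificial
    selection in crops that are only a few sexual generations from the wild.
    Implements VCF site filtering (depth, quality, minor allele frequency,
    missingness), sliding-window nucleotide diversity, Watterson's theta,
    Tajima's D and Weir-Cockerham FST, a cross-population composite likelihood
    ratio (XP-CLR style) sweep scan, composite top-percentile sweep calling
    with block merging and gene annotation, folded site frequency spectra,
    LD decay, Ks-based divergence dating, and per-sample runs of homozygosity
    with terminal-run detection. Ships a forward Wright-Fisher simulator of a
    wild population and a cultivar population founded through a small-founder
    bottleneck with implanted hard sweeps, so the whole pipeline is testable
    end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
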