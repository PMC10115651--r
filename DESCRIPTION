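Package: metevol
Title: Timing and Mode of Metastatic Divergence from Multi-Region Tumour Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the evolution of metastasis from multi-region
    tumour sequencing. Given per-case mutation-cluster tables with
    phylogenetic cancer cell fractions (phyloCCF), the package classifies the
    timing of metastatic divergence (early versus late, relative to the last
    clonal sweep in the primary tumour) by phylogenetic, region-based,
    loss-of-heterozygosity and whole-genome-doubling criteria; quantifies the
    effect of primary-tumour undersampling on those calls; classifies
    dissemination as mono- or polyclonal and mono- or polyphyletic; identifies
    metastasis-seeding mutation clusters with a leaf-up algorithm; estimates
    per-region clone proportions and a clonal dispersion index; and runs
    paired primary-metastasis selection analyses for mutations and somatic
    copy-number events with exact or Monte-Carlo multinomial tests. A
    deme-based spatial agent model of tumour growth under a dynamic selection
    landscape, with emulated whole-exome read-outs and metastasis seeding at
    prespecified primary sizes, relates divergence timing to primary tumour
    size. A synthetic-data generator produces clone trees with known ground
    truth so every analytic stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
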