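Package: pearlmap
Title: SNP Linkage-Map Construction and Analysis for Pedigreed Pearl-Oyster Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses dense biallelic SNP linkage maps from mixed
    phase-known and phase-unknown pedigrees of the kind used for the silver-lipped
    pearl oyster (Pinctada maxima). Provides marker-level data-integrity filters,
    extraction of informative meioses, two-point recombination-fraction and LOD
    estimation (sex-average and sex-specific), layered linkage-group formation,
    haplogroup collapsing, hierarchical likelihood-based marker ordering with a
    moving-window order refinement and a double-recombinant audit, Kosambi
    sex-average/female/male map distances, genome-coverage estimation,
    heterochiasmy and segregation-distortion tests with FDR control, linkage
    disequilibrium (r2, D') decay summaries, and a pedigree/genotype simulator
    that emulates the mapping-family design and supplies ground truth for
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
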