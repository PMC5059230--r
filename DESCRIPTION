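Package: orscpop
Title: Population Genomics of the Oryza rufipogon Species Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for SNP-based population genomics of
    wild rice (the Oryza rufipogon species complex) and its cultivated
    relatives: genotype filtering, windowed Weir-Cockerham Fst, nucleotide
    diversity and Jukes-Cantor-corrected genetic distances, neighbor-joining
    trees, linkage-disequilibrium decay with equal-sample-size sub-sampling
    confidence bands, Mantel isolation-by-distance tests, statistical-parsimony
    chloroplast haplotype networks with ancestral/derived allele calling,
    ancestry-threshold admixture classification with species-label concordance,
    and extended-haplotype detection of domestication-gene introgression.
    Includes a structured-population genotype simulator (Balding-Nichols with
    optional block-mosaic linkage) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
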