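Package: microShare
Title: Household Sharing Analysis of Human and Dog Microbiota
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying microbiota sharing among cohabiting
    hosts from 16S rRNA phylotype (OTU) tables. Implements unweighted and
    weighted UniFrac, Faith's phylogenetic diversity, depth filtering and
    rarefaction, principal coordinates analysis, a dyadic within- versus
    between-household rank permutation test (ANOSIM-like R), one-way
    PERMANOVA on distance matrices, shared-phylotype accounting with
    taxon-family breakdowns, age-trajectory regression against an adult
    baseline, Gibbs-sampling source attribution of sink communities, and
    a hierarchical Dirichlet-multinomial simulator of household-structured
    communities (families, couples, children, dogs, multiple body sites)
    for power studies and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    vegan,
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
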