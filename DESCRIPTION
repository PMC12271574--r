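Package: plumedpr
Title: Phylogenetic Diversity-Productivity Analysis Along Estuarine Plume
    Salinity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the bacterial diversity-productivity
    relationship along estuarine-plume salinity gradients. Implements
    abundance-weighted mean pairwise phylogenetic distance with an
    independent-swap null model (SES_MPD), compositionality-robust
    co-occurrence networks (SparCC) with per-sample subnetwork topology,
    community cohesion and a phylogenetic complementarity proxy,
    abundance-weighted salinity niches with overlap and difference indices,
    phylogenetic binning at a fixed branch-length threshold, group
    comparisons with Benjamini-Hochberg correction, hierarchical
    partitioning of explained variance, and a seeded synthetic-community
    generator that emulates a plume-to-open-sea gradient with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    jsonlite,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
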