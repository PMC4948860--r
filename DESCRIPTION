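Package: stageshift
Title: Diversity Shifts Across Plant Life Stages in Fragmented Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers community assembly processes from shifts of species
    richness and Faith's phylogenetic diversity between plant life stages
    (seedling, sapling, tree) on habitat islands. Observed per-island
    diversity differences across a life-stage transition are standardized
    against randomization null models (an individual-pool fixed-margin
    resampling null for species diversity and the independent-swap null for
    phylogenetic diversity), significant shifts are mapped to candidate
    ecological mechanisms (environmental filtering, dispersal limitation,
    density dependence, interspecific competition), and regression trees
    attribute the standardized shifts to island attributes (area, shape,
    isolation). Includes a synthetic metacommunity generator with known
    assembly processes for validation, landscape shape/isolation metrics,
    and Blomberg's K for phylogenetic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
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
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
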