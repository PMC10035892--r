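Package: cmfpt
Title: Class Mean First Passage Times for Two-Class Cell Mixing Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how two cell populations are spatially intermixed on
    a lattice using class mean first passage times (CMFPT) of random walkers,
    normalised against a random-relabelling null model. Ships an agent-based
    simulator of an expanding wild-type tumour population invaded by a mutant
    sub-clone (selection s, mutation timing n_mut, bounded cell pushing q,
    coupled birth/death), artificial two-class pattern generators, quadrat
    Shannon entropy and mean shortest-distance comparator statistics, and
    approximate Bayesian grid-search inference of (s, n_mut, q) for an
    observed pattern by nearest-neighbour matching in log-CMFPT space.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
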