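Package: semleap
Title: Distributional Semantic Spaces for Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact distributional semantic spaces over biomedical
    concept-occurrence and predication (subject-predicate-object) data and runs
    literature-based discovery on them. General associations are learned by
    reflective random indexing over concept and term occurrences; predication
    structure is encoded by predicate-specific coordinate permutations of sparse
    ternary elemental vectors (predication-based semantic indexing). On top of
    these spaces the package provides screened open discovery (nearest indirect
    neighbors), closed discovery by vector combination, second-order "logical
    leap" retrieval with middle-term recovery, Pathfinder network scaling of
    result neighborhoods, and a time-sliced evaluation harness with a synthetic
    corpus generator that plants known discovery structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
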