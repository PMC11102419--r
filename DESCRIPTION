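Package: divindex
Title: Phylogenetic Diversity Indices and Their Robustness to Extinction
Version: 1.0.0
Authors@R:
    person("divindex", "maintainers", email = "divindex@example.org",
           role = c("aut", "cre"))
Description: Tools for computing and analysing phylogenetic diversity
    indices on rooted edge-weighted trees using exact rational arithmetic.
    Implements the Fair Proportion and Equal-Splits indices, a general
    framework for indices defined by ratios of allocations at interior
    vertices, classification of indices as interior/boundary and
    rigid/non-rigid, constructive edge-length assignments that make
    species rankings reverse completely after a prescribed extinction
    event, and necessary-condition checks plus a reversible family of
    trees under the ultrametric (clock-like) constraint.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
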