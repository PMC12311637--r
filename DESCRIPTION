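Package: fracnet
Title: Interdomain Co-Occurrence Networks for Size-Fractionated Microbial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for size-fractionated marine microbial
    communities (bacteria, pico-protists, nano-protists): cross-fraction
    ASV deduplication, alpha/beta diversity with permutation tests
    (PERMANOVA, Mantel, partial Mantel), Levins' niche breadth,
    compositionally-aware sparse co-occurrence network inference with
    StARS stability selection, network robustness/efficiency/keystone
    analysis, predator-prey biomass ratios, and partial least squares
    path modeling with bootstrap inference. Includes a seeded synthetic
    community generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
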