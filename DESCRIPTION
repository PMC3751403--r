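Package: rangediv
Title: Geographic Diversification Analysis with State-Dependent
    Birth-Death Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether speciation and extinction rates
    differ between geographic regions on dated phylogenies.  Assigns
    species to biogeographic zones from occurrence records and zone
    polygons, reconstructs ancestral ranges under a two-state Markov
    (Mk2) model, fits binary-state (BiSSE) and geographic-state (GeoSSE)
    speciation-extinction models by maximum likelihood with
    incomplete-sampling corrections and constrained-model ladders
    compared by AIC, computes lineage-through-time curves, the gamma
    statistic and clade age-richness regressions, and replicates any
    analysis over a posterior sample of trees.  Includes forward
    (Gillespie) simulators for constant-rate and state-dependent
    birth-death trees, tip states, incomplete sampling and occurrence
    records, so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    geosphere,
    jsonlite,
    Rcpp,
    sp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
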