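Package: invascape
Title: Invasion Risk Scoring, Drivers, and Maximum-Entropy Habitat
    Suitability for Port-Scale Plant Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing plant invasions at the
    scale of a trade port and its hinterland. Computes plot-level community
    statistics (relative height, cover and abundance, importance values,
    Shannon-Wiener diversity, occurrence rates, family composition,
    community-type summaries), scores invasion risk with a weighted
    multi-criteria indicator system, fits a generalized linear model of
    invader importance on community diversity and bioclimatic predictors,
    fits an L1-regularized presence-background maximum-entropy species
    distribution model with jackknife, percent-contribution and
    permutation-importance diagnostics, classifies suitability surfaces
    with Fisher-Jenks natural breaks, and compares habitat areas across
    future climate scenarios. Ships seeded generators for synthetic
    landscapes, occurrences, vegetation surveys and risk scoresheets so
    the whole pipeline runs reproducibly without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
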