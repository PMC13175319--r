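Package: fucflux
Title: Flux-Balance Strain Design for l-Fuculose Production in Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constraint-based analysis of l-fuculose production in engineered
    Escherichia coli. Provides a BiGG-dialect JSON reader/writer for
    constraint-based metabolic models, extension of a host network with the
    l-fuculose biosynthesis pathway (FucA aldol condensation of lactaldehyde
    and dihydroxyacetone phosphate, dephosphorylation by innate sugar
    phosphatases) together with its competing routes (FucI, FucK, TpiA, FucO,
    AldA), a deterministic flux-balance and flux-variability engine with an
    exhaustive vertex-enumeration oracle for small networks, simulation
    campaigns (aerobic/anaerobic scenarios, oxygen-uptake sweeps,
    glucose:lactaldehyde ratio scans, and gene-deletion strain series), and
    titer/yield/fold-improvement metrics for fermentation time courses.
    Ships a self-contained synthetic mini-core network and fermentation
    simulator so every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
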