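Package: dogpop
Title: National Pet Dog Population Estimation from Multi-Source Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the size, density, and demographic structure of a
    national pet dog population from overlapping animal registries (breed
    registries, veterinary practices, insurers, welfare charities). Provides
    a synthetic multi-source registry generator with known ground truth,
    record cleaning and breed normalisation, a four-phase deduplication
    (entity resolution) procedure, a hierarchical Bayesian N-mixture
    abundance model with source-level detection probabilities driven by
    human population size (marginalised likelihood, adaptive
    Metropolis-within-Gibbs in compiled code), and posterior aggregation
    into regional and country totals, per-capita densities, and
    within/between demographic partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
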