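Package: pacnet
Title: Potential Apparent Competition in Plant-Pollinator Visitation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies potential interspecific and intraspecific competition
    among flower-visiting bee species that share floral resources. Builds daily
    quantitative bipartite visitation networks from transect records, computes
    Mueller's potential apparent competition (PAC) index per network, estimates
    effective relative abundances from interaction frequencies under the
    mass-action principle, assesses interaction sampling completeness with the
    Chao2 incidence estimator, and fits Gaussian mixed models relating the
    competition indices to floral density, competitor abundance, proboscis
    length, flowering period and year. Includes a synthetic multi-year
    visitation-data generator with trait-matching preferences and seasonal
    floral phenology, so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    tools,
    glmmTMB,
    lme4,
    car,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
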