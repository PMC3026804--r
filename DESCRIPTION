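Package: pollinet
Title: Individual-Based Pollination Networks and Their Functional Consequences
Version: 0.1.0
Authors@R:
    person("Pollinet", "Developers", email = "pollinet@example.org", role = c("aut", "cre"))
Description: Builds individual-based (plant x plant) pollination networks from
    visitation surveys, quantifies their architecture (NODF nestedness,
    connectance, normalized degree, clustering, pollinator functional
    specialization and hub scores) against two bespoke null models (a
    cell-probability CE null and a frequency-based random-visitation null),
    and relates architecture to plant population performance with spatially
    explicit statistics (lagged-predictor spatial autoregression, partial
    Mantel tests). Includes a synthetic-data module that generates
    multi-population visitation surveys, foraging-mode-structured pollinator
    assemblages and a downstream multiplicative fitness chain with
    controllable coupling between network architecture and performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
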