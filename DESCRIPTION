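Package: sagescape
Title: Spatial Conservation Prioritization for Sagebrush Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for systematic conservation planning in sagebrush-steppe
    and similar raster landscapes. Derives planning units (intact and degraded
    habitat) from cover time series, builds cost and feature layers including
    omnidirectional circuit-theory connectivity surfaces, and solves minimum-set
    reserve-selection problems with per-feature targets, boundary-length
    penalties with an edge factor, locked-in constraints, and an
    uncertainty-weighted sensitivity sweep based on coefficient-of-variation
    layers. Ships a seeded synthetic-landscape generator so every stage of the
    workflow can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
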