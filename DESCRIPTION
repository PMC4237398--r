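Package: fragscape
Title: Landscape Fragmentation Dynamics from Categorical Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based landscape fragmentation analysis for categorical
    land-cover rasters: connected-component patch delineation and the class
    metrics mean patch area (AREA_MN), largest patch index (LPI), edge
    density (ED) and edge-to-area ratio (EDGE_AREA); forest-change
    classification between two dates with deforestation-only,
    reforestation-only and urban-masked counterfactual scenarios; tiling of
    a landscape into large square cells with per-cell indices, covariate
    summaries and land-cover increments; maximum-likelihood estimation of
    spatial-error regressions on k-nearest-neighbour weights with
    AIC-guided term retention; and quadratic peak-shift inference for urban
    sprawl gradients. Includes a seeded synthetic-landscape generator
    (modified random clusters, edge-biased reforestation, interior-biased
    deforestation, distance-decayed urban growth, spatial-error data with
    known parameters) so the whole pipeline is testable without external
    map data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
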