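Package: medaccess
Title: Spatial Accessibility and Equity of Tiered Medical Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-level analysis of spatial accessibility to medical
    services on gridded demand data. Builds typed road/rail transport
    graphs, computes origin-destination travel costs with an improved
    node-cost rule (off-network access legs with a walk/feeder speed
    switch and a Euclidean short-circuit), and derives six accessibility
    surfaces: nearest space-time cost to any facility (primary care),
    two-step floating catchment area (2SFCA) indices with power-law
    distance decay for secondary care, and a hierarchical own-city plus
    provincial-capital gravity model for tertiary hospitals. Downstream
    tools cover global and local Moran's I with permutation inference
    and LISA cluster labels, Lorenz curves and population-weighted Gini
    coefficients, county-level group-equity correlations, percentile
    composition ratios, and sensitivity sweeps over catchment threshold
    and capacity weight. Includes a reproducible synthetic study-region
    generator emulating a core-periphery province, since typical source
    data (road vectors, facility registries, census grids) are not
    redistributable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
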