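Package: gclstm
Title: Graph-Convolutional LSTM Early-Warning Model of Regional Food-Access Diabetes Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds regional early-warning surfaces for type 2 diabetes risk from
    food-environment visit behaviour. Geotagged check-in records are spliced onto
    point-of-interest (POI) attributes by text similarity and haversine distance,
    weekly visit frequencies are counted per POI, and each map tile becomes a graph
    whose nodes are POIs and whose edges carry the food-access categories of
    diabetes cases. A graph convolutional network with an LSTM over weekly steps is
    trained end-to-end to score tiles, and geographically weighted category
    matrices plus layered GeoJSON heatmaps are exported. A self-contained synthetic
    world generator with a planted risk signal makes the whole pipeline runnable
    and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
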