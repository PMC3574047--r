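Package: netweave
Title: Fabric-Style Linear Layouts for Large Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lays out networks with nodes as horizontal line segments, one
    per row, and edges as vertical line segments, one per column. Provides
    the degree-ordered breadth-first default layout, a neighborhood
    similarity ("connectivity") layout with cosine or Jaccard coefficients
    and a sticky placement chain, shadow-link duplication so every node
    owns a complete zone of its incident edges, link grouping by relation
    suffix tags, first-neighbor subset views with order-preserving
    compression, deterministic SVG and raster rendering, readers and
    writers for Cytoscape SIF and node/link order files, and seeded
    Erdos-Renyi and Barabasi-Albert graph generators for testing layouts
    at scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    png,
    withr,
    jsonlite
Config/testthat/edition: 3
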