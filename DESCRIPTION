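Package: follinet
Title: Network-Theoretic Analysis of In Vitro Folliculogenesis Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing literature-curated molecular interaction
    databases of in vitro folliculogenesis (ivF) as directed signaling
    networks. Reads five-column interaction tables (source, interaction,
    target, species, PMID), builds simple directed graphs, characterizes
    their topology (clustering, characteristic path length, power-law
    degree fits), identifies network controllers (degree hubs above the
    mean-plus-one-standard-deviation threshold, shortest-path-tree
    bottlenecks, and their intersection), stratifies nodes into input,
    processing and output layers by the in/out degree ratio, runs
    targeted versus random node-removal attack experiments with collapse
    detection, and detects subpopulations among controllers with kernel
    density estimation. A layered preferential-attachment generator
    produces annotated synthetic databases with the same statistical
    structure, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
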