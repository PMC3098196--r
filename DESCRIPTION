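Package: toolboxevo
Title: Toolbox Models of Metabolic Network Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulators and theory for the toolbox model of metabolic
    network evolution, in which organisms grow their metabolic repertoire
    by horizontally acquiring whole pathways from a universal reaction
    network. Implements the model on Galton-Watson branching trees
    (critical and supercritical) together with its mean-field
    layer-occupation theory, on linearized reaction graphs obtained by
    random spanning trees or shortest-path trees, and on realistic
    branched reaction hypergraphs with AND-gated multi-substrate
    reactions, scope expansion, and minimal-pathway backtracking. Includes
    a parser for the KEGG map-formula reaction dialect, a synthetic
    universe generator with empirically calibrated substrate/product
    multiplicities, pathway-geometry statistics, and log-binned power-law
    scaling analysis of the number of regulated pathways versus network
    size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
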