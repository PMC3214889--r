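Package: ppidiscover
Title: Dense-Subgraph Mining of Protein Interaction Networks for
    Assembly-Factor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds seed-centred protein-protein interaction networks from
    heterogeneous tab-delimited snapshot files, partitions them with an
    overlapping cohesiveness-growth algorithm and a disjoint k-core
    vertex-weighting algorithm, and reports the residual anchor-connected
    proteins left after subtracting dense sub-clusters from a parent
    cluster as candidate assembly factors of a protein complex.  Includes
    a planted-module synthetic network generator so that every pipeline
    stage can be validated end to end without external database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
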