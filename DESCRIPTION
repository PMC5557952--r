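Package: mircascade
Title: Influence Diffusion Analysis of Disease-Specific miRNA Interaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease-specific miRNA-miRNA interaction networks (DMINs)
    from probabilistic edge lists and fold-change expression tables, derives
    influence edge weights by a slack-minimizing linear program over node
    expression scores (or by constant rescoring), estimates each miRNA's
    cascading influence under the Independent Cascade model by Monte-Carlo
    simulation with an exact live-edge enumeration oracle for small networks,
    and aggregates influence across the diseases of a category by edge-wise
    intersection (product of edge scores) or cumulative union (averaged
    coverage percentages) to rank candidate causal miRNAs.
License: MIT
Encoding: UTF-8
Imports:
    boot,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
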