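Package: pathprop
Title: Network Propagation of Copy-Number Alterations for Pathway Disruption Analysis
Version: 0.1.0
Authors@R: person("pathprop", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Integrates gene-level copy-number alteration scores with a
    protein-protein interaction network by label propagation to quantify
    pathway disruption across cancer types. Provides symmetric-normalized
    diffusion of GISTIC-style gene scores, mean-member pathway activity
    scoring, permutation-based empirical significance with
    Benjamini-Hochberg adjustment, selection of commonly and specifically
    disrupted pathways, hypergeometric overrepresentation baselines,
    co-disruption clustering, network-view export, and a synthetic-data
    generator for end-to-end benchmarking without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
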