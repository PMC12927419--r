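Package: grgsim
Title: Phenotype Simulation on Genotype Representation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A graph-based phenotype simulator for phased genotype hard
    calls. Genotypes are encoded losslessly as a directed acyclic graph
    (a genotype representation graph) whose traversals compute
    genotype-matrix-vector products without materializing the matrix.
    On top of the graph, a four-stage pipeline samples causal variants,
    draws effect sizes from built-in or user-supplied distributions,
    computes additive genetic values (raw or on the standardized
    genotype matrix), adds environmental noise calibrated to a target
    narrow-sense heritability, and optionally normalizes phenotypes or
    converts them to binary traits under a liability threshold model.
    Reads phased VCF, writes GCTA-style .par and .phen files, and ships
    a command-line interface plus deterministic synthetic-data
    generators used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    vcfR,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
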