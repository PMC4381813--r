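Package: meta3cr
Title: Metagenomic Chromosome Conformation Capture (meta3C) Analysis and
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing chromosome-conformation-capture (3C/Hi-C)
    read pairs from mixed microbial communities: in-silico restriction
    digestion and binning schemes, construction and sequential component
    normalization (SCN) of contact matrices, species deconvolution of
    contigs by Louvain community detection on the contact graph, 3D genome
    reconstruction by shortest-path distance geometry, coverage-based
    detection of segmental duplications and plasmid contact profiling, and
    a fully seeded synthetic meta3C community simulator with truth labels
    for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    igraph,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
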