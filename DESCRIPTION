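Package: scaffoldmap
Title: Hierarchical Scaffold Classification and Treemap Visualization of
    Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies small molecules into an eight-level scaffold
    hierarchy (molecular frameworks, graph frameworks, ring topologies,
    ring-connectivity abstractions and ring counts), builds a background
    hierarchy from any SMILES/SDF compound library, computes diversity
    statistics over the tree (branching-factor bins, per-level child-count
    percentiles, top-k scaffold coverage), and lays out a scaffold's
    children as a squarified treemap with frequency-based size and color
    encodings, exported as SVG or JSON. Includes a seeded synthetic
    library generator with known-by-construction scaffold chains, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    utils,
    stats,
    grDevices,
    tools,
    ChemmineR,
    ChemmineOB,
    igraph,
    data.table,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
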