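Package: fusionclock
Title: Dating Gene Fusion Events by Reconciliation and Clock Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference toolkit for dating gene fusion events
    on a species phylogeny. Provides a synthetic-data generator (clock-like
    sequence evolution on a chronogram, gene-family birth, duplication,
    fusion and loss histories, genome layouts, calibration-curve tables),
    pairwise distance and local-alignment utilities, neighbor-joining tree
    building with bootstrap support, strict-clock least-squares divergence
    dating with calibration points, Nei-Gojobori Ks paralog dating,
    bi-modular fusion-gene detection and classification, gene-tree versus
    species-tree LCA reconciliation with Dollo loss inference and
    fusion-origin bracketing, microsynteny comparison via reciprocal best
    hits, and LOD-thresholded metabolite presence calling. The worked
    scenario is the evolution of a cytochrome P450-oxidoreductase fusion
    gene and its biosynthetic gene cluster in poppies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
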