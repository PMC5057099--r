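Package: rpr3d
Title: Recurrence-Plot-Based Reconstruction of 3D Chromosome Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs unique three-dimensional chromosome structures from
    binary Hi-C contact maps by treating the contact map as a recurrence plot:
    neighbor-set (Jaccard) local distances are assigned to contact edges, the
    metric is completed by all-pairs shortest paths, and coordinates are
    recovered by classical multidimensional scaling. Includes tools for
    binning and binarizing contact data, chromosome backbone augmentation,
    chaotic toy systems (Lorenz, Roessler) and synthetic chromosome fibers for
    validation, and downstream structure comparison (Procrustes alignment,
    distance-matrix and windowed 3D correlations, radial profiles, similarity
    dendrograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
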