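Package: bcrsim
Title: Simulation and Analysis of Paired Single-Cell B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing paired heavy/light-chain
    B-cell receptor (BCR) repertoires at single-cell resolution. Provides a
    toy murine immunoglobulin germline model with the Igl cassette
    architecture, a repertoire simulator with empirical (frequency-preset)
    and mechanistic (sequential kappa-then-lambda rearrangement with
    receptor editing) modes, V(D)J annotation with junction extraction and
    a four-way productivity classifier, repertoire skew statistics
    (isotype and lambda-family usage, V/J gene usage with Pearson
    correlation, V-J cassette pairing, editing signatures, CDR3
    properties, clonotype tables), and Levenshtein-distance-1 CDR3
    similarity networks for clonal-expansion detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
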