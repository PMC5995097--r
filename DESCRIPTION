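Package: branchallom
Title: Branch-Level Allometry of Orchard Tree Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing power-law allometric scaling in the
    aboveground architecture of woody plants, built around per-branch
    measurement tables from orchard trees. Ingests and validates rooted
    branching topologies, computes morphological characteristics (length,
    mass, surface area, volume) at the segment, path and subtree branch
    classifications, estimates allometric exponents by standardized
    (reduced) major axis regression with analytic 95% confidence
    intervals, compares linear against quadratic log-log fits by AICc,
    and classifies empirical exponents against the theoretical
    predictions of the Flow Similarity and West-Brown-Enquist branching
    models. A synthetic self-similar tree generator with known scaling
    exponents, measurement noise and pruning operators supports
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
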