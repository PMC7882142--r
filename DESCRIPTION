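Package: quarrypal
Title: Quantitative Analyses for Partial Marine-Reptile Skeletons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analyses that accompany
    the description of a partial plesiosaurian skeleton: comparative
    proportional body-length estimation from incomplete vertebral columns,
    gastrolith (clast) shape statistics (Maximum Projection Sphericity,
    Oblate-Prolate index, four-class shape assignment), circular statistics
    for axial element orientations (Rayleigh, Rao's Spacing, Watson's U2 and
    Kuiper's uniformity tests with asymptotic and Monte-Carlo p-values), and
    morphological maximum-parsimony phylogenetics (Fitch optimization,
    random-addition and tree-bisection-reconnection heuristic search,
    ensemble consistency and retention indices, strict and Adams consensus,
    wildcard-taxon detection, reduced consensus, nonparametric bootstrap).
    Seeded synthetic-data generators produce inputs with the statistical
    structure each stage assumes, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
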