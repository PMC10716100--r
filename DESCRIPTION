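Package: episheet
Title: Cell-Based Mechanics of Epithelial Monolayers on Elastic Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the short-timescale elastic mechanics of an epithelial
    monolayer coupled to a deformable substrate. Cells are closed 2D polygons
    evolved by overdamped Runge-Kutta dynamics under cortical, junctional,
    pressure, membrane, contact, edge, division and focal-adhesion forces; the
    substrate is a triangular spring lattice calibrated against a bonded
    elastic layer, with rupturable focal adhesions linking the two. Includes
    virtual experiments (epithelium growth by cell division, single-cell
    micromanipulation on uniform and graded-stiffness substrates, optogenetic
    junction contraction) and field analyses that turn trajectories into
    displacement maps, force maps, axis profiles and junction-length metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
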