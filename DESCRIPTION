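Package: qsarpipe
Title: 2D/3D-QSAR Modelling with Heuristic Descriptor Selection, Gene
    Expression Programming and CoMSIA-Style Field Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end quantitative structure-activity relationship
    (QSAR) toolkit for small-molecule inhibitor series.  Provides activity
    transformation and train/test bookkeeping for IC50 tables, stepwise
    multiple-linear-regression descriptor selection (the CODESSA-style
    heuristic method) ranked by a composite fitness function, gene
    expression programming (GEP) symbolic regression over Karva-notation
    genomes, CoMSIA-style Gaussian similarity fields with partial
    least-squares modelling and leave-one-out q2 component selection,
    external-validation statistics, seeded synthetic-data generators with
    planted signals, and a pipeline driver tying the stages together.
    Reference 2D-QSAR models for a published quinazoline FGFR4-inhibitor
    series are built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    ChemmineR,
    mixOmics,
    optparse
Config/testthat/edition: 3
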