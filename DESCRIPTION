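Package: agemyo
Title: Heterogeneity, Composition and Trajectory Analysis for Ageing Muscle Single-Cell Atlases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bespoke analysis stages for multimodal single-cell and
    single-nucleus studies of skeletal muscle ageing: matched-downsampling
    transcriptional and epigenetic heterogeneity ("noise") statistics over
    expression-invariant genes, marker-module scoring with hierarchical
    myofibre-type classification of myonuclei, cell-type composition analysis
    via a Poisson generalized linear mixed model with grand-mean fold changes
    and local true sign rates (LTSR), and pseudotime bin/trend analysis with
    k-means gene-trend clustering. Ships a negative-binomial synthetic-atlas
    generator with ground-truth labels so every stage is testable without
    access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Epigenetics, GeneExpression, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agemyo-package.R'
    'composition.R'
    'io.R'
    'noise.R'
    'fibre.R'
    'simulate.R'
    'trends.R'
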