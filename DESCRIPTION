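Package: ensembleGCEA
Title: Ensemble-Based Gene Category Enrichment for Spatial Transcriptomic Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene category enrichment analysis (GCEA) for spatially embedded
    transcriptomic atlas data, with ensemble-based null models. Implements
    gene-score resampling against the conventional random-gene null as well
    as randomized-phenotype ensemble nulls built from independent random
    maps or spatially autocorrelated maps drawn from a spatial-lag model.
    Provides Gene Ontology parsing (OBO structure, GAF annotations),
    annotation propagation along is_a edges, category false-positive-rate
    auditing under phenotype ensembles, category diagnostics (within-category
    coexpression, distance-dependent correlated gene expression and its
    exponential-decay fit), and a synthetic-atlas generator with controlled
    coexpression and spatial autocorrelation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    minpack.lm,
    jsonlite,
    data.table,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'atlas-io.R'
    'scoring.R'
    'surrogates.R'
    'nulls.R'
    'gcea.R'
    'cfpr.R'
    'ontology.R'
    'synthetic.R'
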