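Package: bloodDeconv
Title: Immune-Cell Deconvolution of Blood Expression Profiles and
    Prognostic Survival Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates immune-cell proportions from bulk gene-expression
    profiles of blood specimens by marker-constrained semi-supervised
    non-negative matrix factorization minimizing generalized
    Kullback-Leibler divergence, and evaluates their prognostic value by
    median-split Kaplan-Meier estimation, log-rank testing and
    multivariate Cox proportional-hazards regression. Also stratifies
    tissue samples into Low/High antigen-presentation groups by
    two-means clustering of an MHC gene panel. Ships a synthetic-data
    generator (cell-type signatures with exclusive marker genes,
    Dirichlet mixtures, proportional-hazards survival cohorts, planted
    two-cluster panels) so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, ImmunoOncology, Survival, Clustering
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bloodDeconv-package.R'
    'methods-accessors.R'
    'deconvolution.R'
    'expression-io.R'
    'survival-stats.R'
    'stratification.R'
    'pipeline.R'
    'synthetic-data.R'
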