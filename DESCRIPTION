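Package: omicslier
Title: Integrative Multi-Omics Prediction of Protein Abundance and
    Post-Translational Outlier Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative modelling of the mRNA -> translation ->
    protein hierarchy across the human cell cycle. Computes sequence-derived
    predictors of protein abundance (codon adaptation index, tRNA adaptation
    index, effective number of codons, reference-free codon usage bias, and
    ProtParam-class physicochemical properties), performs L1-regularised and
    filter-based feature selection, predicts per-phase protein abundance with
    linear and gradient-boosted tree regressors under cross-validation, flags
    hard-to-predict proteins as putative post-translationally regulated
    outliers from squared log2 residuals, and tests outlier sets for
    enrichment of post-translational modification sites against a
    subsampling null distribution. Includes a seed-deterministic synthetic
    data generator emulating the statistical structure of cell-cycle
    multi-omics datasets so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    glmnet,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'codons.R'
    'types.R'
    'protein-properties.R'
    'codon-metrics.R'
    'io.R'
    'feature-matrix.R'
    'stats-corr.R'
    'model-selection.R'
    'predictor.R'
    'outliers.R'
    'ptm-enrichment.R'
    'simulate.R'
    'headline.R'
    'cli.R'
    'omicslier-package.R'
    'RcppExports.R'
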