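Package: vitroembed
Title: Biologically Informed Molecular Embeddings for Imbalanced Toxicity Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns molecular embeddings by jointly pretraining a small
    bidirectional transformer encoder on SMILES token masking,
    physicochemical descriptor regression, and sparse binarized in vitro
    assay panels, then models severely imbalanced in vivo toxicity
    endpoints (e.g. drug-induced liver injury readouts) with a
    frozen-encoder plus multitask MLP protocol. Provides a weighted
    focal loss family for class imbalance, Bemis-Murcko scaffold
    cross-validation splits, precision-recall-first evaluation, and a
    seeded synthetic corpus generator with planted structure-activity
    signal so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: OpenBabel command line tools (obabel) for fingerprints
RoxygenNote: 7.3.3
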