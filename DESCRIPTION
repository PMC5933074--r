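Package: semisrc
Title: Semisupervised Sparse Representation Decoding of fMRI Brain States
Version: 0.1.0
Authors@R: person("semisrc", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multivoxel pattern decoding of block-design fMRI with sparse
    representation classifiers. Provides a gradient-projection l1 solver,
    residual and average-coefficient sparse representation classifiers,
    a shrinkage linear discriminant classifier, confidence-gated
    self-training that grows the training dictionary from unlabeled test
    volumes, random-subspace online ensembles, a SimTB-style block-design
    fMRI simulator, and an experiment pipeline (feature selection,
    normalization, classifier comparison, threshold-coefficient sweep)
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
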