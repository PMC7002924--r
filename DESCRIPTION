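Package: mdrelevance
Title: Feature Importance from Molecular Simulation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts interpretable per-feature and per-residue importance
    from conformational ensembles sampled by molecular simulation. Provides a
    common featurization layer (Cartesian coordinates, full or reduced inverse
    interatomic distances, contact-change and range filters, min-max scaling),
    six supervised and unsupervised importance estimators (PCA loadings,
    symmetric Kullback-Leibler divergence, random-forest mean decrease
    impurity, and multilayer perceptron, autoencoder and restricted Boltzmann
    machine attribution via layer-wise relevance propagation), a synthetic
    multi-state toy-model generator with known ground truth, and a
    quantitative benchmark with find-all and ignore-irrelevant accuracy
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
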