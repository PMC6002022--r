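Package: odorlex
Title: Odor Character Prediction from Mass Spectra via Semantic Descriptor Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting the odor character of a chemical from its
    electron-ionization mass spectrum. Verbal odor descriptors from a binary
    sensory catalog are clustered by UPGMA hierarchical clustering on either
    catalog-column correlation dissimilarity or word-embedding cosine
    dissimilarity; the catalog is converted to cluster labels by an OR rule; a
    sigmoid feed-forward autoencoder compresses spectra into low-dimensional
    feature vectors and a mapping network predicts cluster labels from them,
    with momentum stochastic gradient descent, L2 weight decay, step-function
    thresholding and five-fold cross-validated true-positive/true-negative
    evaluation. Includes a seeded synthetic-data generator that reproduces the
    mutually exclusive descriptor usage that makes column correlations vanish
    for semantically similar descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
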