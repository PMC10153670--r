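Package: stnet
Title: Hybrid Sigmoid/Spiking Neural Networks with Joint SpikeProp Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two hybrid spatio-temporal classifier architectures
    that couple a sigmoid artificial neural network with a spike-response-model
    (SRM) spiking neural network through non-trainable spike-time coding
    layers: a concatenated form (ANN in front, SNN behind, joined by
    reciprocal coding) and a parallel form (an SNN path and an ANN path
    spliced in the coding layer, followed by a classifying SNN). Both are
    trained jointly by gradient descent, with SpikeProp-style temporal
    backpropagation through threshold-crossing firing times. Includes
    Gaussian population coding and linear time-delay coding of features,
    time-to-first-spike prediction, dataset preprocessing (min-max
    normalization, mean imputation, spectral band averaging, IDX image
    ingestion), a seedable synthetic-data generator, repeated stratified
    k-fold cross-validation, and competition-rank aggregation of test
    accuracies across approaches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
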