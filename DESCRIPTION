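Package: crowdopt
Title: Optimal Crowd Meta-Classification by Cell-Table Outcome Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines any family of binary classifiers ("machines") into a
    single meta-classifier, the optimal crowd. The joint binary predictions
    of the machines partition the training data into cells; a test point is
    routed to its cell and the known training outcomes there are averaged
    to estimate its class-1 probability, falling back to all nearest
    occupied cells under Hamming distance when the cell is empty. Includes
    a registry of random forest, k-nearest-neighbour and support vector
    machine configurations, synthetic-feature augmentation, a balanced
    stratified five-fold cross-validation benchmark with percent-error
    reporting, and Gaussian-mixture simulators with closed-form Bayes error
    for optimality experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    class,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
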