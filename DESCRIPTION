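Package: ccknn
Title: Cross-Cluster kNN QSAR Modelling with Simulated-Annealing Descriptor Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Variable selection and activity prediction for QSAR descriptor
    tables. Compound activities are predicted as the exponentially
    distance-weighted mean of the k nearest neighbours in a selected
    descriptor subspace, model quality is scored by leave-one-out
    cross-validated q-squared, the descriptor subset is optimised by
    Metropolis simulated annealing, and the neighbourhood size k is chosen
    by a sweep over small k. Includes range scaling of heterogeneous
    descriptor columns, an exhaustive-search oracle, a multi-restart
    ensemble runner, a synthetic QSAR benchmark generator with known ground
    truth, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
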