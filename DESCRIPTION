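Package: hyperbrain
Title: Dynamic Hyperbrain Networks and Evolving Hypergraph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of dynamic hyperbrain networks from regional
    brain-signal time series and their classification with evolving
    hypergraph neural networks. Regional time series are segmented with a
    sliding window; within each window every region is expressed as an
    l1-penalized sparse linear combination of the remaining regions,
    solved on the least-angle-regression lasso path, and the nonzero
    coefficients define one hyperedge per region. The resulting sequence
    of hypergraph snapshots is classified at the subject level with an
    evolving hypergraph convolutional network or an evolving hypergraph
    attention network that aggregates each node's hyperedge neighbourhood
    across adjacent snapshots. Includes a synthetic cohort generator with
    planted sparse structure, stratified k-fold cross-validation, and
    parameter sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
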