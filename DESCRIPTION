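Package: netdistill
Title: Distilling Gene Regulatory Network Topologies from Trained
    Recurrent Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains small bounded neural-network synthesis functions inside
    a discrete-time gene-expression integrator so that the resulting
    dynamical system achieves a prescribed biological function (adaptation,
    controlled oscillation, morphogen-driven patterning), then distills the
    learned regulation logic into signed network topologies by in-silico
    link knockdown, sparsifies networks to minimal functional motifs by
    iterative link deletion and retraining, validates candidate topologies
    as Hill-function dynamical models via random-parameter robustness
    screening, and benchmarks link inference on continuous-state cellular
    automata against a linear autoregressive baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
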