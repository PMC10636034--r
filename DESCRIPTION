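Package: fracctrl
Title: Structural Controllability of Fractional-Order Dynamical Networks
Version: 0.1.0
Authors@R:
    person("fracctrl", "developers", email = "fracctrl@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse how long-term power-law memory changes the
    resources needed to control a dynamical network. Implements the
    Grunwald-Letnikov discretisation of discrete-time fractional-order
    network dynamics, generic (structural) rank of the T-step
    controllability matrix via vertex-disjoint linkings in a time-expanded
    graph, minimum driven-node selection for Markov and long-memory
    dynamics under a time-to-control budget, seeded synthetic network
    generators (Erdos-Renyi, Barabasi-Albert, Watts-Strogatz), ensemble
    sweep experiments, and the sandbox multifractal spectrum of a network
    with its width and height summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
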