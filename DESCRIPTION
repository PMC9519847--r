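Package: synaptopt
Title: Connectivity Optimization for Diluted Hopfield Attractor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates autoassociative (Hopfield) memory networks with binary,
    diluted connectivity and exact integer Hebbian weights, and optimizes which
    synapses exist rather than their strengths. Each neuron's presynaptic
    connection row is tuned by simulated annealing under two quadratic cost
    functions -- noise reduction (drive the crosstalk on the aligned local
    field to zero) and signal reinforcement (drive it to a positive target) --
    or by an online greedy add/prune rule interleaved with pattern loading.
    Includes storage-capacity search with the all-patterns-retrieved criterion,
    basin-of-attraction profiling, aligned-local-field statistics, and
    structural analyses of optimized connectivity such as the conditional
    connection probability given the Hebbian weight.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
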