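Package: gdinfer
Title: Graphical Directed Information for Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Model-free inference of directed functional connectivity in
    multichannel neural time series via graphical directed information (GDI):
    pairwise directed information conditioned on the past activity of the
    remaining nodes of the network, estimated with a classifier-based
    Donsker-Varadhan representation of the Kullback-Leibler divergence.
    Includes excitatory/inhibitory sign inference through time-lagged partial
    correlation, spike-train binning, seeded synthetic network generators
    (linear-Gaussian, nonlinear, logistic-Bernoulli spiking) with analytic
    oracles, and an end-to-end pipeline producing signed connectivity graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
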