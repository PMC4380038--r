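Package: ensdist
Title: Nonstationary Markov Substitution Models and the
    Expected-Number-of-Substitutions Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic distances for nonstationary, time-homogeneous
    continuous-time Markov nucleotide substitution processes. Implements the
    expected number of substitutions (ENS) along an edge as the integral of
    the instantaneous substitution rate against the evolving state
    distribution, computed by an augmented matrix-exponential construction.
    Provides maximum-likelihood fitting of a nested hierarchy of triad
    models (GTR, GTR with discrete-gamma rate heterogeneity, and a general
    nonstationary model with per-edge rate matrices and a free root
    distribution), clock-constrained variants with a likelihood-ratio
    relative-rate test, paralinear and LogDet distances from empirical
    joint distributions, goodness of fit by the G statistic with a
    parametric bootstrap, identifiability screens (diagonal-largest-in-column
    and rate-matrix mapping uniqueness), and a triad alignment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    tibble
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
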