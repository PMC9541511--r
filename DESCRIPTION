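Package: noduleTrace
Title: Stochastic Character Mapping of Nodule-Type Evolution Under a
    Constrained Three-State Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ancestral-trait inference for root-nodule symbiosis on
    time-calibrated phylogenies. Implements a constrained three-state
    continuous-time Markov model (nonnodulating / fixation-thread /
    symbiosome) with an absorbing nonnodulating state, maximum-likelihood
    rate estimation by Felsenstein pruning, exact endpoint-conditioned
    path sampling by uniformization, stochastic character mapping of
    full trait histories, and summarization into node-state proportions,
    majority-rule branch transitions, loss rates per million years and
    transition age bounds. Includes a synthetic-data generator
    (birth-death chronograms plus forward-simulated trait histories with
    observation masking) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    Matrix,
    optparse,
    phytools,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
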