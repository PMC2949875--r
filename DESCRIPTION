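Package: biogeodec
Title: Dispersal-Extinction-Cladogenesis Range Evolution and Bayesian
    Ancestral-Area Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood and parsimony tools for historical biogeography on
    time-scaled phylogenies. Implements the dispersal-extinction-cladogenesis
    (DEC) model with adjacency-restricted range states and directional
    dispersal hypotheses, maximum-likelihood rate estimation and ancestral
    range-inheritance reconstruction; dispersal-vicariance (DIVA) parsimony by
    exact dynamic programming; Bayesian multistate (Mk) ancestral-area MCMC
    with node fossilization and Bayes-factor node support; harmonic-mean
    marginal-likelihood estimation with log10 Bayes-factor comparison tables;
    AIC and Akaike weights; offset-gamma fossil calibration and node-age
    priors; and seeded simulators (Yule trees, DEC and Mk tip data,
    conjugate-normal likelihood traces) providing ground-truthed test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
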