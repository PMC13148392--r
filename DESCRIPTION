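Package: recombsim
Title: Stochastic Breeding-Program Simulation Under Modified Recombination Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-in-time simulation of doubled-haploid recurrent selection
    breeding programs used to quantify how 2- to 8-fold increases of the
    recombination rate affect genetic gain, genetic and genic variance
    dynamics, and genomic-prediction accuracy. Provides a gamma-renewal
    crossover-interference meiosis engine operating on centimorgan genetic
    maps, a synthetic founder generator with realistic linkage-disequilibrium
    decay, additive trait architectures calibrated to unit additive variance,
    ridge-regression BLUP (RRBLUP) genomic prediction with spectral REML
    variance-component estimation, and replicated breeding-scheme experiments
    (phenotypic versus genomic selection, training cadence, model reuse across
    recombination-rate changes, and merged multi-generation training sets).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
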