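Package: deceptIPD
Title: Evolutionary Iterated Prisoner's Dilemma with Information-Theoretic Deception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of the iterated prisoner's
    dilemma (IPD) in which agents can evolve memory-tampering deception
    behaviours (degradation, corruption, denial, subversion) at a heritable
    per-game cost. Provides the seven classic memory-driven IPD strategies,
    the four deception operators with counterfactual success accounting, a
    birth-death evolutionary loop with score-weighted breeding, two-point
    crossover and evolved mutation probabilities, parameter-sweep experiment
    drivers with equilibrium classification, closed-form least-squares fitting
    of a bilinear compartment (SIR-like) diffusion model to trait-fraction
    time series, and supporting information-theoretic measures (Shannon
    capacity, information content, compression-based similarity,
    Kullback-Leibler divergence, mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
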