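Package: v1rex
Title: Conductance-Based Modelling of Embryonic Renshaw Cell Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-compartment Hodgkin-Huxley-type model of embryonic V1
    interneuron (Renshaw cell) excitability, built around the balance between a
    persistent sodium conductance (GNap) and a delayed-rectifier potassium
    conductance (GKdr). Provides deterministic fixed-step Runge-Kutta and
    stochastic (hybrid Gillespie, discrete Markov channel) simulation engines,
    in-silico current-clamp and voltage-clamp protocols with pharmacological
    manipulations, numerical bifurcation analysis (Hopf points, folds of limit
    cycles, two-parameter activity maps, bistability regions), firing-pattern
    phenotyping (single spiking, repetitive spiking, mixed events, plateau
    potentials), hierarchical clustering of firing features with
    silhouette-based cluster-number selection, Hill dose-response fitting, and
    seed-deterministic synthetic data generators for all pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
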