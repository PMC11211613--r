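Package: thetagamma
Title: Neural-Mass Simulation of Theta-Gamma Coupled Sequence Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hippocampus-inspired network of neural-mass units in
    which gamma oscillations nested in a theta rhythm encode and replay
    temporal sequences of episodes. Provides the four-population neural-mass
    unit (pyramidal, excitatory, slow- and fast-GABAergic interneurons) with
    gamma, theta, and working-memory presets; a three-layer architecture
    (working memory, auto-associative layer, hetero-associative output layer)
    paced by an external theta generator; Hebbian and anti-Hebbian training of
    the plastic synapse classes with incoming-weight normalization; retrieval
    and isolation (imagination, dreaming, schizophrenia-like) operating modes;
    and cycle-by-cycle scoring of sequence replay success.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
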