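Package: canet
Title: Spiking Cortical Network Simulation of Reward-Modulated Cell Assembly Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-area, brain-constrained spiking neural network of
    frontal (motor) and parietal (somatosensory) cortices. Excitatory cells are
    leaky integrate-and-fire neurons with adaptation, paired with graded local
    inhibitory cells and area-level global inhibition; sparse, patchy,
    topographic connectivity links the areas along documented cortico-cortical
    tracts. Hebbian plasticity follows the Artola-Broecher-Singer (ABS)
    LTP/LTD rule, optionally modulated by a binary dopamine-like reward signal
    that boosts the learning rate and lowers the LTP threshold. The package
    implements the full two-phase protocol (associative motor-haptic pattern
    training, then reward-gated learning driven by spontaneous cell-assembly
    ignitions), cell-assembly identification and ignition analysis,
    interquartile-range outlier screening, and the repeated-measures ANOVA
    battery with sphericity testing used to quantify reward-seeking ignition
    bias.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ggplot2,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
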