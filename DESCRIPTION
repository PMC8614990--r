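Package: ipmqbd
Title: Integrated Process Models for Quality-by-Design Bioprocess Development
Version: 0.1.0
Authors@R: person("IPM", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Builds integrated process models (IPMs) of downstream
    bioprocess purification chains by concatenating per-unit-operation
    specific-clearance regression models, the output pool concentration of
    one unit operation feeding the next as specific load concentration.
    Monte-Carlo simulation of process-parameter and model uncertainty
    yields out-of-acceptance (OOA) probabilities for critical quality
    attributes at drug substance.  On top of the simulation engine the
    package provides a grid-based one-at-a-time parameter sensitivity
    analysis, an automated FMEA severity-ranking linearization based on
    the ratio of the simulated OOA slope to a critical-effect slope, and
    proven-acceptable-range (PAR) derivation at a configurable critical
    OOA level.  A synthetic process generator with known ground truth
    supports testing of every pipeline stage, and a command-line driver
    ties fitting, simulation, sensitivity analysis, ranking and PAR
    reporting into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    optparse,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
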