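Package: secmotion
Title: Single-Particle Motion Analysis of Secretome mRNA Translation on the ER
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify the translation state of ER-associated secretome
    mRNAs from single-particle trajectories. Implements per-trajectory mean
    squared displacement (MSD) confinement classification, ensemble MSD fitting
    of apparent diffusion coefficients with localization error, multi-component
    displacement cumulative-distribution mixture fits, ER tubule junction
    detection with organelle proximity statistics, FRAP and optogenetic
    recruitment kinetics, and a Monte Carlo Brownian/confined-motion simulator
    that provides ground-truth fixtures for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
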