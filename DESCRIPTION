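Package: motorunit
Title: Quantification of Motor-Unit Assays: Axonal Transport, Myofiber
    Contraction, NMJ Integrity and Motor-Neuron Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for quantifying compartmental motor-unit
    cultures and related in vivo readouts: single-particle track
    kinematics of axonal cargo (instantaneous and average velocity, stop
    detection, run lengths, mean squared displacement, directionality and
    co-transport), burst-based calling of contracting myofibers from
    intensity-over-time traces, colocalization-based scoring of
    neuromuscular-junction health and innervation, mutant-protein
    aggregate density and muscle-fiber diameter summaries, and per-explant
    motor-neuron survival fractions with the classical group statistics
    (pooled-variance t test, one-way ANOVA with Fisher's LSD). A seeded
    synthetic-data module emulates the statistical structure of each assay
    so every pipeline stage can be exercised end to end with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
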