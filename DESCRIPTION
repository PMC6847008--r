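Package: gqunfold
Title: Single-Molecule Quantification of Helicase-Mediated G-Quadruplex Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how G-quadruplex-stabilizing small-molecule
    ligands inhibit helicase-mediated unfolding from single-molecule
    fluorescence data. Implements dual-threshold hysteresis event counting on
    smFRET trajectories with pooled rate estimation and molecule-level
    bootstrap uncertainty, Gaussian-mixture fitting of FRET-efficiency
    histograms, and a cumulative-activity assay based on counting
    surface-bound fluorophores across a time-lapse. A synthetic-data module
    simulates two-state trajectories and spot time-lapses with known ground
    truth so every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    minpack.lm,
    generics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
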