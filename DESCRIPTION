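Package: semdrive
Title: Small-Molecule-Inducible Self-Eliminating Gene Drive Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-node simulation of CRISPR homing gene drives carrying a
    small-molecule-inducible self-eliminating mechanism (SEM). Builds
    validated inheritance cubes for five SEM designs (cis- and trans-acting,
    autosomal and X-linked) in three resistance flavors, embeds them in a
    stage-structured mosquito lifecycle expressed as a stochastic Petri net,
    and simulates the system with Gillespie, tau-leaping, and mean-field
    samplers using first-order sparsity-aware hazard evaluation. Timed
    release and spray events drive the induction schedule, and ensemble
    analysis produces long-format summary tables suitable for ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
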