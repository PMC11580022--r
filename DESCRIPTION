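Package: memtide
Title: Membrane Tension Propagation and Tether Mechanics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for optical-trap membrane-tether experiments on
    secretory cells: conversions among tether force, membrane tension and tether
    radius; trap-stiffness calibration from hydrodynamic oscillation records; a
    diffusive membrane-tension propagation model with Darcy permeability set by
    immobile transmembrane obstacles, including forward simulation of double-tether
    protocols and tension-diffusivity fitting; FRAP recovery fitting yielding tracer
    diffusivity and immobile fractions; tether-drag kinematics with stall detection;
    and an exo-endocytosis area-balance model of activity-driven tension dynamics.
    Seeded synthetic-data generators emulate every experiment with known ground
    truth so the full chain is testable end to end.
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
    Matrix,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
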