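Package: thermosalmon
Title: Coupled River Temperature and Juvenile Salmonid Bioenergetics Modelling
Version: 0.1.0
Authors@R: person("Quinault", "Modelling Group", email = "thermosalmon@example.org",
    role = c("aut", "cre"))
Description: Process-based one-dimensional river water-temperature simulation
    (solar and riparian shading, surface and streambed heat fluxes, steady
    low-flow hydraulics with tributary mixing) coupled to a Wisconsin
    bioenergetics model of juvenile Pacific salmon and trout growth. Includes
    a seeded synthetic-river generator emulating a lake-fed coastal reach,
    riparian-vegetation and delta-method climate scenarios, calibration by
    candidate-model selection with bias/RMSE/Nash-Sutcliffe fit statistics,
    and thermal-habitat summaries (7DADM, life-stage threshold exceedance,
    factorial ANOVA of scenario growth).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
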