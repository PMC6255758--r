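Package: kneedrive
Title: Kinetic Versus Kinetic-Kinematic Driving of Tibiofemoral Contact Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale quasi-static simulation of tibiofemoral contact during
    the stance phase of gait, built to compare kinetic (forces and moments) and
    kinetic-kinematic (forces and prescribed rotations) ways of driving a knee
    joint model. Cartilage is represented by a field of one-dimensional
    transversely isotropic poroelastic contact columns (an elastic-foundation
    discretization with through-thickness consolidation), ligaments by
    prestrained bilinear springs, menisci by elastic wedge spacers anchored by
    horn springs, and an optional point-patella extensor mechanism. Four
    driving modes with increasing simplification are provided, together with a
    synthetic geometry and gait generator, compartment-averaged stress, strain
    and pore-pressure summaries, model-comparison metrics, and a parametric
    sweep of the quadriceps force scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
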