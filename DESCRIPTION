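Package: retorq
Title: Micro-Macro Finite-Element Simulation of Implant Removal Torque
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the removal torque of cylindrical implants from the
    micromechanics of a roughness-derived surface feature. A conical feature
    is fitted to areal surface roughness parameters (Sa, Sdq, Sdr) of an
    acid-etched titanium surface, a first-order hexahedral finite-element
    model of the embedding polymer unit cell is solved under frictionless
    unilateral contact against the rigid feature, fracture is modelled by
    deletion of elements whose von Mises stress reaches the polymer yield
    strength, and the resulting reaction-force curves are combined through an
    analytic torsion layer model into a removal-torque-versus-rotation
    prediction with fracture-progression reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
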