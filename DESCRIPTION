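Package: vadsim
Title: Reduced-Order Biomechanics of Vacuum-Assisted Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation of the maternal soft-tissue mechanics of
    vacuum-assisted delivery. Implements a transversely isotropic
    hyperelastic constitutive model for pelvic floor muscle with a
    generalized-Maxwell (quasi-linear viscoelastic) extension, linear
    elastic and Neo-Hookean companion models for perineal structures, a
    displacement-controlled pull/rest traction protocol, and a reduced-order
    model of two hiatal rings distended by an axisymmetric fetal head.
    Includes Hertzian plate-compression calibration of the fetal-head
    Young's modulus, synthetic anatomy and compression-curve generators,
    phase and scenario reporting, and a command-line pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
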