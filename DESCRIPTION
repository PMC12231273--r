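Package: paranmr
Title: Field-Dependent NMR Shifts of Paramagnetic Molecules in Solution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes field-dependent solution NMR shifts of paramagnetic
    molecules from spin-Hamiltonian parameters (electron spin S, g matrix,
    zero-field-splitting tensor D) and per-nucleus hyperfine data. Two routes
    are implemented: an exact finite-field approach that Boltzmann-averages
    the induced field over electronic states and molecular orientations
    (Lebedev quadrature on the unit sphere), and a second-order approach
    built from analytic free-energy derivatives, namely the shielding tensor
    sigma, the magnetic susceptibility tensor chi, and the fourth-order tau
    tensor that governs the direct (saturation-type) field dependence.
    Fermi-contact and point-dipole pseudocontact coupling operators are
    provided, together with a seeded synthetic spin-system generator,
    numerical-derivative oracles for the analytic sum-over-states tensors,
    and YAML/XYZ/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
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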