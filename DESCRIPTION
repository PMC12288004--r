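Package: mlmmti
Title: Mechanically Embedded ML/MM Simulation and Thermodynamic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale molecular simulation and free-energy engine for
    hybrid ML/MM potentials under mechanical embedding. One region of a
    system is described by an opaque machine-learning interatomic potential
    (a single total energy plus forces, with no bonded/nonbonded split) and
    the remainder by a classical force field; the two regions interact
    through Coulomb and Lennard-Jones terms. Provides velocity Verlet and
    Langevin (BAOAB) integrators with SHAKE constraints and stability
    diagnostics, and a thermodynamic-integration framework in which only
    the region-region coupling is scaled by lambda while the omitted
    intra-ML perturbation is compensated by a reorganization-energy
    correction. Ships independent free-energy oracles (Bennett acceptance
    ratio, exact low-dimensional configurational integrals), end-point
    trajectory analyses (Kabsch RMSD, B-factors, a Still-style generalized
    Born binding estimator), and seeded synthetic fixtures with closed-form
    answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
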