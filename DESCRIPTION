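Package: rbcphase
Title: Phase-Field Simulation of Erythrocyte-Erythrocyte Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Two-cell phase-field model of erythrocyte mechanics and
    fibrinogen-mediated adhesion. Each cell is a smooth order-parameter
    field on a periodic 3D lattice evolving under Canham-Helfrich bending
    elasticity, cell-cell surface adhesion, hard-core repulsion and
    surface/volume penalty constraints, integrated with a semi-implicit
    Fourier-spectral scheme (FFTW backend). Includes equilibrium-shape
    relaxation and classification (stomatocyte, discocyte/oblate, prolate),
    aligned and offset collision protocols, and force, contact-area,
    adhesion-energy and detachment-work observables on the scale of
    single-cell micropipette and AFM measurements.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
SystemRequirements: fftw3
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
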