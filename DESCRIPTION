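Package: cardiomaze
Title: Microstructural and Discrete Monodomain Models of Fibrotic Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electrical propagation in two-dimensional cardiac tissue at
    subcellular resolution and quantifies how microfibrosis turns a tissue region
    into an ectopic pacemaker. Provides a myocyte-resolved microstructure (a
    tileable 32-cell template on an 8 micrometre grid with membrane, cytoplasm and
    three gap-junction connection types), a heterogeneous monodomain solver using
    Godunov operator splitting (explicit-Euler reaction, implicit-Euler
    finite-volume diffusion), an equivalent discrete cell-network model obtained by
    series/parallel reduction of the gap-junction resistor network, a port of the
    Bondarenko et al. (2004) mouse ventricular ionic model plus a fast two-variable
    surrogate, seeded random fibrosis ensembles, and analysis tools for reentry
    detection, activity classification, conduction velocity and directional
    percolation thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    withr
Config/testthat/edition: 3
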