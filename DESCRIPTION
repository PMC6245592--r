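Package: psfcav
Title: Coupled Hydrodynamics and Photosynthetic-Factory Kinetics for
    Microalgae Culture Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microalgae growth in two-dimensional culture systems by
    coupling the three-state photosynthetic factory (PSF) kinetic model of
    photosynthesis and photoinhibition to an incompressible lid-driven-cavity
    flow and a Beer-Lambert light field. Provides the full and fast-reduced PSF
    dynamics with steady-state and stiffness analysis, a streamfunction-vorticity
    cavity solver, an operator-split advection-diffusion-reaction transport
    solver for the species fractions, Lagrangian particle tracing with
    irradiance histories, and growth-performance metrics (normalized
    productivity index, specific growth rate, Damkohler number). Reproduces the
    hydrodynamically induced flashing-light enhancement of photosynthetic
    productivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
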