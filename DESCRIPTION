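Package: gyropatch
Title: Gyrotactic Microbe Individual-Based Modelling and Patchiness Analysis in Turbulent Mixed Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates populations of gyrotactic, non-gyrotactic motile and
    passive microbes advected through three-dimensional unsteady velocity
    fields, and quantifies the microscale patchiness that emerges from the
    coupling of motility and turbulence. Provides analytic test flows, a
    divergence-free kinematic-turbulence generator with a convective
    mixed-layer depth structure, and a reader for gridded netCDF velocity
    fields; a Lagrangian integrator for the coupled swimming-direction and
    position dynamics; periodic three-dimensional Voronoi tessellation for
    local concentration estimates and the patch concentration enhancement
    factor Q; and diagnostics including Kolmogorov scales, stability and
    swimming numbers, effective velocities and orientation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    ncdf4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
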