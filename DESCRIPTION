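Package: cardiowave
Title: Monodomain Simulation of 2D Cardiac Electrical Wave Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates action-potential propagation in two-dimensional
    cardiac tissue with the Beeler-Reuter membrane model using the
    Drouhard-Roberge reformulation of the fast sodium current, coupled by
    anisotropic (fiber-rotated) diffusion on a rectilinear grid with
    no-flux boundaries and explicit Euler time stepping.  Provides
    interchangeable, equivalence-tested compute backends (scalar
    reference, gather, scatter, cache-tiled, and strip-parallel stencil
    kernels), stimulation protocols that initiate plane waves, single
    spiral-wave (rotor) reentry and rotor breakup, activation-map /
    conduction-velocity / action-potential-duration readouts, a
    nodes-per-second benchmark harness, a flat-text configuration format,
    and a documented binary snapshot format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
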