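Package: spobs
Title: Self-Propelled Particles Moving Through Elastically Tethered Obstacles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying collective motion of self-propelled particles
    (SPPs) in an elastic obstacle environment. Implements a stochastic
    individual-based simulator of Vicsek-type aligning particles interacting
    with beads tethered by Hookean springs, the one-dimensional nonlocal
    macroscopic density equation obtained in the stiff-spring limit together
    with asymptotic obstacle-density closures, linear stability analysis with
    dispersion relations and pattern-size prediction, the obstacle-induced
    effective interaction kernel W = phi' * phi', and pattern metrics
    (particle-to-grid density estimation, peak counting, travelling-wave
    speed measurement).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
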