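Package: aucflow
Title: Automated GMP Sedimentation-Velocity Workflow for Analytical
    Ultracentrifugation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A headless, reproducible sedimentation-velocity pipeline for
    analytical ultracentrifugation (AUC) under Good Manufacturing Practices
    (GMP) constraints. Provides a finite-volume Lamm-equation simulator that
    stands in for the instrument, second-by-second rotor timestate
    bookkeeping and verification, intensity to pseudo-absorbance conversion
    against an air-region reference, automated meniscus detection and data
    editing, grid-based non-negative least-squares decomposition over a
    sedimentation-coefficient / frictional-ratio grid with time- and
    radially-invariant noise removal, Monte Carlo refinement, a
    tolerance-based Pass/Fail reporting module, and an autoflow supervisor
    that tracks each experiment through the staged workflow with session
    locking and crash reattachment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
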