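Package: pbforce
Title: Finite-Difference Poisson-Boltzmann Electrostatics and
    Disordered-Tail Flexibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how intrinsically disordered, highly charged
    C-terminal tails (such as the tubulin E-hooks) steer the binding of a
    protein partner. Provides trajectory-ensemble flexibility statistics,
    a finite-difference linearized Poisson-Boltzmann solver on regular
    grids with DelPhi-style parameterization, surface-potential
    summaries, electric field line tracing, net electrostatic force
    profiles over a rigid separation scan, and a synthetic-data module
    (toy charged bodies, anchored Gaussian tail trajectories, analytic
    two-charge systems) so every stage is testable without external
    structures or simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
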