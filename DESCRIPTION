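Package: slmassembly
Title: Closed-Loop Control of Lattice Self-Assembly via Stochastic
    Landscape Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rejection-free (n-fold way) kinetic Monte Carlo simulation of
    multi-target self-assembly of labelled particles on a bounded square
    lattice, together with a closed-loop control protocol that detects
    kinetic traps in near-real time and rescues them.  Energy trajectories
    are segmented on the fly into piecewise-linear trends; a learning phase
    builds a stochastic landscape of segment dwelling time versus trend and
    identifies the near-zero-trend trap region; during controlled runs,
    transient interaction-energy shocks (division of all binding energies
    by a drive amplitude rho) are applied whenever the latest trend falls
    in the trap region, boosting assembly yield and shortening the time to
    first assembly.  Includes equilibrium and controlled ensemble scans,
    first-assembly statistics, assembly-phase classification, and
    before/during/after shock distance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
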