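Package: minratchet
Title: Brownian-Ratchet Simulation of Bacterial Chromosome Segregation by
    Membrane Tethering Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lattice Monte-Carlo simulator of entropy-driven segregation of
    two bacterial chromosomes, modelled as self-avoiding ring polymers
    (bond-fluctuation method) in rod-shaped confinement, with transient
    membrane tethering of chromosomal segments under uniform, static-gradient,
    oscillating-gradient, or measured MinD-profile tethering fields (a
    Brownian ratchet).  Includes ensemble observables (centre-of-mass
    trajectories and distributions, axial density profiles, radius of
    gyration, force-distance probe), synthetic pole-to-pole MinD oscillation
    profiles, and in-vivo style analysis metrics: nucleoid separation depth
    and distance from 1D intensity profiles, and mean-squared-displacement
    and apparent diffusion estimation from particle tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
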