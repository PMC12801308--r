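Package: fespath
Title: Free-Energy Landscapes, Transition Paths and Kinetics from
    Well-Tempered Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping conformational free-energy landscapes of
    small proteins from enhanced-sampling simulations at desk scale:
    conformational clustering of trajectories (PCA + k-means) to motivate
    collective-variable choices, a well-tempered metadynamics engine
    coupled to an overdamped Langevin sampler on analytic model
    potentials, free-energy-surface reconstruction from hills files by
    bias summation, basin detection by topographic persistence, minimum
    free-energy paths by the nudged elastic band method, and
    Eyring-Polanyi transition-state kinetics.  Includes a synthetic
    two-helix trajectory generator with backbone geometry so the whole
    chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
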