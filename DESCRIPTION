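Package: axoncross
Title: Stochastic Multiscale Simulation of Microtubule-Neurofilament
    Organization in Axonal Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Brownian-dynamics simulation of an axonal cross-section in
    which microtubules, neurofilaments and transiting membranous
    organelles interact as soft disks through excluded-volume repulsion,
    boundary confinement and motor-mediated elastic coupling, with
    stochastic cargo kinetics (neurofilament binding, unbinding and
    turnover; organelle arrival, axial transit and multi-microtubule
    engagement). Includes the analysis statistics used to quantify
    cytoskeletal organization: radial distribution function, occupancy
    probability distribution with Gaussian fit, and pairwise
    microtubule distance summaries, together with preset scenarios that
    reproduce reversible microtubule-neurofilament segregation when
    neurofilament transport is impaired.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
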