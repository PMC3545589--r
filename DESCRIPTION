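Package: nanoporesim
Title: Ion Permeation, Blocker Binding and Feasibility Modelling for
    Nanotube-Channel Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling single-file ion conduction through
    functionalized carbon-nanotube channels and its use in a
    blocker-release biosensor. Provides one-dimensional potential of mean
    force (PMF) profiles built from printed anchor features, a synthetic
    umbrella-sampling generator with a weighted histogram analysis method
    (WHAM) reconstruction, dissociation constants of pore blockers from
    the cylinder-restrained PMF integral, an overdamped Langevin
    (Brownian dynamics) permeation engine with concentration-clamped
    reservoirs yielding current-voltage and current-concentration
    behaviour, a steady-state Smoluchowski flux solver used for
    cross-checking, and device-level arithmetic (Stokes drag, flux
    conversion, channel-density scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
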