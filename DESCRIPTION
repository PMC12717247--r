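Package: mompsim
Title: Particle-Based Stochastic Simulation of Mitochondrial Outer Membrane
    Permeabilization Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale particle-based reaction-diffusion simulation of the
    regulation of mitochondrial outer membrane permeabilization (MOMP) by a
    reduced MCL-1/tBID/BAK interactome. Provides a 3D periodic model cell with
    configurable rectangular mitochondria (regular, random, polarized,
    surface-varied and fragmented arrangements), Brownian dynamics of cytosolic
    particles with probabilistic membrane (retro)translocation, lateral membrane
    diffusion with face transitions, mesoscopic binding-radius reaction
    simulation at single-mitochondrion resolution with a deterministic
    mass-action oracle, variance-heterogeneity statistics (Levene,
    Brown-Forsythe, Kruskal-Wallis with Dunn's post-hoc, Mann-Whitney,
    D'Agostino-Pearson), image-based mitochondrial size quantification, and
    synthetic-data generators plus a reproducible pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    car,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
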