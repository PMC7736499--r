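Package: papsim
Title: Stochastic Simulation and Quantification of Perisynaptic Glutamate
    Spillover and Astroglial Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how perisynaptic astroglial processes (PAPs) shape
    extrasynaptic glutamate signalling at hippocampal CA3-CA1 synapses. Provides
    a particle-based Monte Carlo simulator of glutamate release, Brownian
    diffusion, glial transporter capture and extrasynaptic NMDA receptor
    activation in a reconstructed synaptic environment under four astroglial
    coverage scenarios; quantification routines for light-microscopy readouts
    (astroglial volume fraction and its exponential decay, FRAP recovery rate,
    point-source effective diffusivity, glutamate-sensor linescan profiles with
    Gaussian FWHM, ratiometric sensor responses); nanoscale coverage statistics
    (3D nearest-neighbour distance densities, proximity classification,
    concentric-shell volume-fraction profiles); two-pathway MK801 cross-talk
    statistics and spillover arithmetic; and seeded synthetic-data generators
    for every analysis input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
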