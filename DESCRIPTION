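Package: gelpress
Title: Coarse-Grained Simulation of Prestress in Composite Polymer Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bead-spring molecular dynamics model of a composite hydrogel: a
    cross-linked star-polymer matrix with embedded self-associating star
    particles in implicit solvent, mimicking the collagen/aggrecan
    organization of articular cartilage extracellular matrix. Builds periodic
    gel topologies, integrates them at constant temperature and pressure with
    Nose-Hoover chain thermostats and an isotropic Martyna-Tobias-Klein
    barostat (compiled inner loop), and measures osmotic (virial) pressure,
    swelling, volume fraction, and bulk modulus. A pipeline assembles
    swelling-pressure curves for composite gels, bare gels, and particle
    solutions and computes the gel prestress (the excess osmotic pressure of
    the embedded particles over the composite at matched swelling), including
    its value at equilibrium swelling. Continuum Flory-Huggins plus elastic
    pressure models can be fitted to simulated or experimental
    swelling-pressure curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
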