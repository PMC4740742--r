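Package: bioelec
Title: Bioelectric Patterning in Gap-Junction-Coupled Cell Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the membrane-potential patterning of small multicellular
    ensembles. A single cell carries one inward- and one outward-rectifying
    voltage-gated channel with Boltzmann gating, giving a bistable resting
    potential; cells sit on a square lattice coupled by ohmic gap junctions and
    are integrated with a constant-matrix semi-implicit (IMEX) scheme. External
    channel-blocker concentration fields rescale the local conductance ratio
    (with optional explicit finite-difference diffusion), and charged
    nanoparticles are allocated over the resulting potential map under a
    Boltzmann equilibrium. Includes scenario presets, delimited-text grid I/O
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
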