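Package: xrrfit
Title: Slab-Model Analysis of Specular X-Ray Reflectivity from Supported
    Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and fitting of specular X-ray reflectivity
    (XRR) from slab models of solid-supported lipid mono- and bilayers,
    with an interpretation layer for protein-membrane composition. Computes
    exact specular reflectivity of layered media by the Abeles transfer
    matrix with Nevot-Croce interfacial roughness (an independent Parratt
    recursion is provided as a cross-check), fits slab stacks to measured
    or simulated curves by seeded differential evolution under box
    constraints with fixed substrate densities, reconstructs continuous
    electron-density profiles, and implements two-component mixing rules
    for head-group hydration, protein volume fraction, displaced waters
    per lipid, and protein volume, electron density and size from an
    amino-acid sequence. A synthetic-curve generator with counting-noise
    models and presets for DOPC and DOPC/DOPS membranes with bound Hsp70
    makes the whole chain testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
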