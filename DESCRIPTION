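Package: btaceflow
Title: Lumped-Parameter Hydraulic Simulation of Balloon-Occluded
    Transarterial Chemoembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Zero-dimensional (lumped-parameter) steady-state simulation of
    the hepatic arterial circulation during balloon-occluded transarterial
    chemoembolization (B-TACE), built around a bench-top hydraulic circuit:
    a constant-head pump, a symmetric bifurcating hepatic artery phantom
    with collateral pathways, and upper/lower reservoirs standing in for
    normal- and tumor-tissue pressure.  Provides Poiseuille resistances,
    Kirchhoff nodal analysis of arbitrary resistive flow networks with an
    independent least-squares verification solver, construction of the
    collateralized hepatic artery tree with the proximal-to-distal balloon
    site map, balloon-occluded arterial stump pressure (BOASP) computation,
    pressure-gradient-effect (PGE) detection, passive injectate tracing,
    treatment-outcome classification, occlusion-site sweeps, and automated
    sizing of the circuit design parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
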