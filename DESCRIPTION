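Package: cardiofib
Title: Electromechanical Simulation of Cardiomyocyte-Fibroblast Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a human ventricular cardiomyocyte electrically and
    mechanically coupled to cardiac fibroblasts. The myocyte combines a ten
    Tusscher-Panfilov 2006 style electrophysiology module with a four-state
    ryanodine-receptor gating scheme, an explicit Ca-troponin C pool with
    cross-bridge cooperativity, and a Hill-type rheological mechanics module;
    fibroblasts follow the MacCannell active formulation extended by a
    length-dependent mechanosensitive current and a passive elastic element.
    Includes pacing protocols, steady-state detection, resting-potential and
    action-potential measurement, classification of early afterdepolarizations
    and extrasystoles, vulnerability diagrams, threshold scans and a
    cooperativity-clamp mechanism experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
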