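Package: hydrolayers
Title: Hydration Layering and Moisture-Crossover Analysis for Hydrophilic
    Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of hydrated hydrophilic polymer systems
    (e.g. softwood xylan): geometric hydrogen-bond detection and class-resolved
    densities, polymer-water distance statistics with double-Gaussian peak
    decomposition and adsorbed-layer assignment, rolling-ball (Shrake-Rupley)
    surface and polymer-water contact areas under periodic boundary conditions,
    property estimators from observable series (heat of adsorption, thermal
    expansion, heat capacity, elastic moduli, Poisson's ratio),
    three-component composite-material decomposition (mixture/parallel/series
    rules), and detection of the moisture-induced crossover via continuous
    two-segment linear fitting. A synthetic-data module generates bead-chain
    polymer configurations, prescribed hydration-shell structure, layer
    volume-fraction schedules and noisy property curves so every stage is
    testable without molecular-dynamics trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
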