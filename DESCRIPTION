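Package: lungbranch
Title: Turing-Type Reaction-Diffusion Model of Lung Branching Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic spatio-temporal model of branch-mode selection in
    the early lung: a Schnakenberg-type Turing system coupling FGF10, SHH and
    the receptor Ptc on an idealized 2D lung-bud cross-section. Provides the
    labelled-domain geometry and structured meshing, a compiled implicit
    reaction-diffusion solver for fixed and axially growing domains
    (advection-dilution transport), linear stability and dispersion analysis
    with a Schnakenberg analytic oracle, FGF10 pattern phenotyping (spot
    detection, lateral/bifurcation classification, branch-event timelines),
    and drivers for the in-silico experiments: parameter sensitivity scans,
    spatial-noise robustness, growth-speed mode selection and mutant
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
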