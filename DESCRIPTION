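Package: uedring
Title: Trajectory-Ensemble and Electron-Diffraction Analysis of a
    Photochemical Electrocyclic Ring-Opening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis tools for excited-state trajectory ensembles of the
    photochemical electrocyclic ring-opening of alpha-terpinene, and for
    forward-modelling the gas-phase ultrafast electron diffraction (UED)
    observables such ensembles predict.  Implements independent-atom-model
    scattering curves sM(s) via the rotationally averaged Debye equation,
    damped sine-transform pair distribution functions (PDFs) and
    time-dependent difference PDFs, coordination-sphere-resolved
    carbon-carbon distance distributions with cis/trans splitting,
    conrotatory planarization/deplanarization angle coordinates,
    wavepacket density projections and population traces, error-function
    onset fitting with trajectory-level bootstrap uncertainties, and a
    seeded phenomenological surrogate generator that emulates the
    statistical structure of nonadiabatic wavepacket simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
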