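Package: demicwave
Title: Three-Population Wave-of-Advance Models of the Neolithic Transition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a three-population reaction-diffusion model of the
    spread of early farming in Europe, in which initial farmers of Near
    Eastern descent, converted farmers of local descent, and
    hunter-gatherers interact through logistic growth, inter-subsistence
    competition, and cultural conversion. Provides the spatially
    homogeneous dynamics with all equilibria and their linear stability
    classification, heuristic minimum traveling-wave speeds from the
    linearization ahead of the front (non-dimensional and dimensional),
    a method-of-lines solver for the one-dimensional system with
    zero-flux boundaries and step initial conditions, front tracking and
    wave-speed estimation, wake-state classification, parameter sweeps
    over competition and conversion strength, and extraction of regional
    demographic trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    deSolve
Config/testthat/edition: 3
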