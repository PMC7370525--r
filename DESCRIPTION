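Package: clonewave
Title: Wright-Fisher Simulation of Driver and Superdriver Clonal Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-generation Wright-Fisher simulator of tumor progression
    with two classes of beneficial mutations: common drivers with selective
    advantage s and rare superdrivers with advantage r = c*s. Clones are
    tracked by their joint (superdriver, driver) mutation counts in an
    exponentially growing cell population, updated each generation by
    fitness-weighted multinomial resampling with per-locus mutation. The
    package runs replicate ensembles over (s, c) parameter grids, measures
    empirical waiting times to clones with given mutation counts, evaluates
    a closed-form waiting-time approximation and linear residual-correction
    models, and quantifies traveling-wave structure of clone abundance
    trajectories (wave detection, widths, peak spacings, and quadratic fits
    yielding location, height, and curvature). A command-line interface
    exposes simulation, grid, waiting-time and wave analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
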