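Package: omgrowth
Title: Stochastic Simulation of Bacterial Outer-Membrane Growth and Virtual
    Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates growth of the Gram-negative bacterial outer membrane as
    a two-dimensional incompressible viscous fluid on a cylinder, driven by
    stochastic bursts of material insertion. Insertion events initiate as a
    Poisson process per unit area, add membrane area at a fixed rate for an
    exponentially distributed duration, and advect all existing material
    through the incompressible source flow they create (method of images on
    the periodic circumference). The package couples the simulator to a
    virtual widefield microscope (3D point-spread-function rendering, camera
    pixelation and noise) and to puncta analytics (spot detection, track
    linking, kymographs, appearance-rate curves, sigmoid metrics and
    divergence statistics), and provides a parameter-space screen over the
    kinetic parameters with consistency classification against user-supplied
    experimental bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
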