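Package: ramtrack
Title: Multiple-Object Tracking with Mutually Repulsive Active Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tracks many moving objects in time-lapse grayscale movies using
    open active contours with fixed target length.  Each object is an elastic
    open contour relaxed against a smoothed image potential; contours are
    coupled across frames into a spatio-temporal membrane solved block-wise
    through Sylvester equations, and coupled across objects by a short-range
    quadratic repulsion that prevents identity merging during close contact.
    Includes an application pipeline for rigid oval walkers (3-point contours,
    jump detection and rescue, Viterbi head-direction correction, velocity and
    relative-position analyses) and one for long flexible gliding rods
    (Hessian ridge/valley pixel classification with EM, enhanced-image
    potentials, 25-point contours with shrink-and-regrow tip growth, gliding
    speed and reversal statistics), plus ground-truthed synthetic movie
    generators and tracking-quality scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    mclust,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
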