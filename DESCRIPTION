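Package: p3ptriangle
Title: Perspective-3-Point Ambiguity Analysis of Triangle Stimuli
Version: 1.0.0
Authors@R: person("Vision", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing the geometric ambiguity of triangle stimuli
    used in 3D shape and depth psychophysics. Implements a Perspective-3-Point
    (P3P) solver that enumerates every 3D interpretation of a planar triangle
    consistent with the three visual angles it subtends at the eye, a
    brute-force verification oracle, constrained uniform samplers over
    triangle shapes and retinal images, Monte-Carlo experiments estimating
    how the number of interpretations depends on image size, and shape-space
    solution-count maps for fixed retinal images, including the stimulus sets
    of two classic shape-constancy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
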