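Package: dxtr
Title: Diffracted X-Ray Tracking Simulation and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for diffracted X-ray tracking (DXT)
    of membrane proteins labelled with gold nanocrystals. Provides a forward
    simulator of rotational (tilt/twist) trajectories and diffraction-spot
    image stacks, spot detection and nearest-neighbour track linking,
    detector-to-angle geometry conversion for the Au(111) Debye-Scherrer ring,
    track-lifetime filtering, time-averaged mean-square-displacement analysis
    with an anomalous-diffusion fit, Gaussian mixture decomposition of angular
    displacement distributions, and two-axis (tilt, twist) probability-density
    maps with condition-versus-condition subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
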