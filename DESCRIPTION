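Package: spatcell
Title: Spatial-Cell Analysis for Open-Arena Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for place, grid, head-direction and
    speed-modulated cells recorded while rodents forage in open arenas,
    including virtual-reality (VR) sessions. Provides trajectory
    preprocessing, locational and directional firing-rate maps, spatial
    autocorrelograms with gridness and grid-scale estimation, Skaggs
    information measures, shuffle-based cell classification against
    time-shifted null distributions, a maximum-likelihood joint
    place-by-direction ('pxd') firing model, LFP theta frequency and
    speed analyses, and two-dimensional theta phase precession via the
    projected distance through field ('pdcd'). A synthetic-session
    generator (random-foraging trajectories, inhomogeneous-Poisson
    spiking from parametric tuning models, speed-coupled theta LFP, and
    paired VR/real manipulations) makes every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    Matrix,
    signal,
    yaml,
    Rcpp,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
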