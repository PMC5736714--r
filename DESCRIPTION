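Package: phototaxr
Title: Agent-Based Simulation of Collective Cyanobacterial Phototaxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates colonies of gliding cyanobacteria (Synechocystis-like
    cells) responding to a directional light source. Cells are finite-size
    discs whose headings are biased toward the light with a fixed per-step
    probability, whose friction depends on the slime (exopolysaccharide) laid
    down on an underlying lattice, and which exert transient pili-mediated tug
    forces on nearby cells. The package provides colony and light-schedule
    initializers, a reproducible simulation engine with checkpoint/resume, and
    trajectory morphometrics (rose plots and circular statistics, kymographs,
    finger segmentation and onset timing, slime-band crossing speed profiles,
    freeloader entrainment), together with tidy exports and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
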