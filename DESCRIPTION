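Package: minifil
Title: Coarse-Grained Electrostatics, Bending and Contact Times for
    Myosin II Minifilament Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the pairwise assembly of nonmuscle myosin II (NM2) rods
    into minifilament precursors. Heavy-chain sequences with a heptad-register
    annotation are converted into linear chains of point charges on the
    0.1456 nm coiled-coil lattice; screened Debye-Hueckel electrostatics give
    interaction energies of staggered parallel and antiparallel rod pairs;
    worm-like-chain bending of the mobile rod is minimized on a grid of arc
    radii and lengths to yield stagger/overlap energy landscapes; and mean
    first-passage times of the overlap coordinate (rolling and zipping of the
    two rods) convert those landscapes into contact-time profiles for homo-
    and hetero-dimers. A synthetic-rod generator with the 196-residue charge
    repeat makes the whole pipeline testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
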