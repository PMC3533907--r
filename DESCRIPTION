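Package: dspacr
Title: Functional Region Prediction from Spatial Autocorrelation of
    Residue Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts functional regions of monomeric proteins by selecting
    the most informative set of homologous sequences. Candidate homolog sets
    are swept over a grid of sequence-identity thresholds and the set
    maximizing the degree of spatial autocorrelation (DSPAC) of conservation
    scores on the protein surface is adopted; conserved-residue clusters are
    then detected with a Local Moran's I statistic of conservation (LMIC)
    under a conditional Monte Carlo permutation null, and predictions are
    scored against catalytic-site-derived functional regions. The surface
    residue graph is built from a Voronoi (Delaunay) tessellation of
    representative side-chain atoms together with a synthetic solvent shell.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
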