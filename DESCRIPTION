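Package: villiwave
Title: Actively Contracting Villous-Tree Model of the Human Placenta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a three-tier voxel model of the stem villi of the human
    placenta (truncus chorii, rami chorii and diffusion-limited-aggregation
    derived ramuli chorii), assigns each villous surface element the
    contraction direction of the axial contractile cells, and propagates the
    contraction into the surrounding continuum as a distance-limited shear
    wave u = xi0*cos(k*r) with shear modulus mu = rho*lambda^2*nu^2.
    Per-slice displacement statistics (magnitude, polar angles phi and theta,
    area fractions, azimuthal uniformity) and the characteristic positions of
    their profiles are computed for the twelve wavelength/propagation-distance
    conditions, together with branching morphometry (centripetal and
    centrifugal orders, bifurcation ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    RNifti,
    readr,
    yaml,
    digest,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
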