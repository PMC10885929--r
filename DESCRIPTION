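Package: hemocond
Title: Anisotropic Electrical Conductivity of Flowing Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a three-dimensional blood velocity field into an
    anisotropic electrical conductivity tensor field. Red blood cells in shear
    flow deform and align by tank-treading; the dominant direction of their
    short axis is estimated either from the eigenvectors of the viscous stress
    tensor or from the Lamb vector (velocity x vorticity), and the two
    principal conductivities follow from Maxwell-Fricke suspension theory with
    shear-dependent deformation and alignment. Includes analytic benchmark
    flows (Poiseuille pipe, modulated swirling pipe, random solenoidal fields),
    finite-difference velocity gradients, metrics quantifying the disagreement
    between the two orientation models, readers and writers for legacy-VTK and
    CSV point fields, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
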