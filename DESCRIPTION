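Package: petdenoise
Title: Post-Reconstruction Denoising of Whole-Body PET Images with a 3D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for convolutional
    post-reconstruction enhancement of [18F]FDG PET images. Generates
    whole-body-like digital phantoms with Poisson count noise, emulates
    list-mode time-splitting of a single acquisition into short
    sub-frames, trains a 3D denoising convolutional network on pairs of
    short-time (noisy) and long-time (clean) reconstructions, and
    evaluates the result with the standard quantitative battery:
    SUVmax/SUVpeak lesion quantification, liver coefficient-of-variation
    noise measurement, Bland-Altman agreement analysis, and
    nonparametric omnibus/post-hoc testing with Bonferroni bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
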