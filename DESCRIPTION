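Package: toemorph
Title: Geometric Morphometrics of Anole Toe and Toepad Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based analysis of lizard toe and toepad shape under a
    fixed 19-landmark / 13-curve digitization template. Reads and writes
    tpsDig-style landmark files, performs generalized Procrustes alignment
    with bending-energy-minimizing sliding of semilandmarks, and provides
    permutation-based shape inference (residual-randomization Procrustes
    ANOVA, morphological disparity, PCA, between-group PCA, and canonical
    variate analysis with a label-randomization null). Landmark-derived
    linear measurements (pad width and length, proximal and total toe
    length, lamella height, outline polygon area, centroid size) feed the
    accompanying univariate tests and type-II general linear models. A
    generative model of toe configurations with known ground truth supports
    calibration and power studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    car,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
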