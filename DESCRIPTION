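Package: parabolaEDA
Title: Fast Parabola Detection in Edge Images with Estimation of
    Distribution Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects parabolic shapes in binary edge images with a
    Univariate Marginal Distribution Algorithm (UMDA): candidate curves
    are built from three edge pixels via the closed-form interpolating
    quadratic and scored by the Hadamard product between the rasterized
    candidate and the edge map.  Includes Hough-transform and RANSAC
    baselines using the same three-point solver, a ground-truthed
    synthetic scene generator with salt-and-pepper noise sweeps and
    Zhang-Suen skeletonization, a grayscale preprocessing chain (mean
    filter, Canny edges, morphological dilation) with foot sectioning
    for plantar-arch and heel parameterization, and normalized-RMSD
    fit-quality metrics with benchmark orchestration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
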