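Package: aodetect
Title: Adjusted Outlyingness Detection for Functional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags magnitude, persistent-shape, isolated-shape and mixed
    outliers in univariate and multivariate functional data observed on a
    common grid.  Each curve is summarised by an adjusted outlyingness (AO)
    vector built from weighted moments of its directional outlyingness --
    an adaptively weighted mean (AMO), a derivative-weighted variance (AVO)
    and a skewness functional (SO) -- reducing functional outlier detection
    to a low-dimensional multivariate problem.  Squared robust Mahalanobis
    distances of the AO cloud are computed with a bootstrap minimum
    covariance determinant estimator or FAST-MCD, and the detection
    threshold is calibrated by a depth-weighted smoothed bootstrap, so no
    Gaussian-process assumption is needed.  Includes simulators for the
    benchmark models (Gaussian, t and skew-t error processes; bivariate
    Matern cross-covariance), evaluation metrics (true/false positive
    rates, precision, F1, AUC), a replication harness, CSV readers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
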