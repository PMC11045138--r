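Package: bpwp
Title: Basis Pursuit Denoising with Polynomial Detrending for Sparse Timeseries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers narrowband oscillations and polynomial trends from
    sparsely and irregularly sampled long-term biomedical timeseries, such as
    hourly rates of inter-ictal epileptiform discharges recorded by implanted
    devices. Builds an orthonormal DCT-II dictionary with a nonuniform,
    low-frequency-densified period grid, jointly estimates sparse spectral
    coefficients and a Vandermonde polynomial trend by L1-ball-constrained
    least squares with variable projection, selects the L1 budget by repeated
    random-split cross-validation, assesses spectral peaks against a
    shuffle-derived noise floor, and evaluates recovered cycles with a
    generalized Morse wavelet reference spectrum, band-limited correlation,
    and circular statistics of event phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
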