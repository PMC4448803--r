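Package: ppcf
Title: Periodic Pair-Correlation Analysis of Lattice Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies clustering and segregation in point patterns extracted
    from cell-biology images. Implements the periodic (wrap-around)
    pair-correlation function on an integer lattice with replicate averaging
    and standard errors, box-kernel binning, and an objective bandwidth
    selection rule based on the dominant wavenumber of the signal's discrete
    Fourier power spectrum. Includes a lattice exclusion-process simulator
    (random non-overlapping placement of square agents and proliferation-driven
    cluster growth) for generating synthetic uniform and clustered patterns,
    plus downstream summaries: cluster-size estimation from the unity crossing
    of the binned signal, exponential growth-curve fitting, and pixel-to-micron
    conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
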