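Package: fusdeconv
Title: Blind Hemodynamic Deconvolution of Functional Ultrasound Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blind deconvolution of multivariate hemodynamic (functional
    ultrasound power-Doppler) time series as a structured block-term
    decomposition of a lagged autocorrelation tensor. Jointly recovers
    region-specific single-gamma hemodynamic response functions and
    uncorrelated latent source signals (task paradigm and additive
    artifacts), selects a stable solution from random restarts by cost
    filtering and clustering of peak latencies, and recovers source time
    courses by truncated-SVD pseudo-inversion. Includes a synthetic-data
    simulator matching the evaluated study conditions, power-Doppler
    preprocessing utilities (SVD clutter filtering, ROI averaging), and
    evaluation metrics (paradigm correlation, peak-latency error, Fano
    factor, correlation images).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
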