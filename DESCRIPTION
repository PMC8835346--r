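Package: dfcstates
Title: Sliding-Window Dynamic Functional Connectivity and Brain-State
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resting-state fMRI dynamic functional connectivity
    (DFC) analysis at the region-of-interest level: temporal preprocessing
    (nuisance regression, detrending, band-pass filtering,
    framewise-displacement scrubbing with spline interpolation),
    sliding-window tapered Pearson correlation with Fisher z-transform and
    1/w filtering, temporal-variability metrics (DFC strength, DFC standard
    deviation, and the low-frequency fluctuation amplitude of connectivity
    series), exemplar-based L1 (Manhattan) k-means clustering of
    connectivity states with elbow-criterion model selection and
    transition-probability estimation, and connection-wise general linear
    model statistics with covariate adjustment and false-discovery-rate
    correction.  A synthetic-cohort generator with known latent state
    structure provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
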