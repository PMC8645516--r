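Package: icnpred
Title: Resting-State Network Connectivity and Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for resting-state fMRI
    treatment-response analysis. Provides a synthetic-cohort generator with
    planted network effects and full ground truth; BOLD signal cleanup
    (Gaussian smoothing, grand-mean scaling, nuisance regression with a
    discrete-cosine highpass and non-reintroduction orthogonalization);
    group-level meta-ICA with signal/noise triage and spatially constrained
    individual back-reconstruction (GIG-ICA); full and ridge-regularized
    partial correlation network matrices with Fisher r-to-z; permutation-based
    group inference with threshold-free cluster enhancement (TFCE) and
    max-statistic familywise error correction; and individual-level response
    prediction via repeated cross-validated linear support vector machines
    with synchronized-permutation familywise error control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    e1071,
    Matrix,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
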