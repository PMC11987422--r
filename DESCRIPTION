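Package: claimvec
Title: Distributed Representations of Claims Codes for Confounding Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Trains skip-gram-with-negative-sampling embeddings over the code
    vocabulary of inpatient administrative claims, compresses each patient's
    admission-day codes into a fixed-length covariate vector by summing code
    weights, and uses that vector as a proxy for unmeasured severity in
    propensity-score-matched comparative effectiveness analyses. Includes a
    latent-severity synthetic claims generator, a bias-injection simulation
    study based on prognostic-score quartile sampling, and a subsample
    bootstrap framework comparing adjustment models on estimate differences
    and confidence-interval widths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
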