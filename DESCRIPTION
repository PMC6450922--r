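Package: fcfingerprint
Title: Functional Connectivity Fingerprinting with Static and Dynamic
    Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying individual subjects and biological sex
    from brain-region time series via functional connectivity (FC)
    fingerprints.  Implements three connectivity estimators (full-run
    Pearson correlation, partial correlation from the inverse covariance,
    and sliding-window dynamic connectivity summarized as K-means states),
    cosine-similarity matching of Fisher-z FC matrices, randomized
    baseline/target identification experiments, leave-one-out sex
    classification against group-average FC, and per-edge statistics
    (consistency, variability, and a mean-based differential power).  A
    synthetic multi-subject cohort generator built on Gaussian graphical
    models with subject, sex, session, and state-switching components makes
    the whole pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
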