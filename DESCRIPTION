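Package: circhrv
Title: Circadian Heart Rate Variability Analysis from 24-Hour RR-Interval
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of circadian rhythms in cardiac autonomic
    function from 24-hour RR-interval recordings. Provides artifact detection
    and cubic-spline beat correction, smoothness-priors detrending, hourly
    5-minute window selection, time-domain, spectral (Welch/Blackman-Harris),
    nonlinear (Poincare, detrended fluctuation analysis, entropies,
    correlation dimension, recurrence quantification) and autonomic
    (Baevsky stress index, PNS/SNS/stress composites) metrics, per-subject
    cosinor rhythmometry (MESOR, amplitude, acrophase) with rhythmicity
    detection, and sex/age group statistics. Includes a synthetic-cohort
    generator with known circadian ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    car,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
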