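Package: hrvdrop
Title: Predicting the Orthostatic Blood Pressure Drop from Short-Term
    Heart Rate Variability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model the systolic blood-pressure change caused by
    standing (orthostatic hypotension) from heart rate variability (HRV)
    measured in the five minutes before the stand. Implements artefact
    detection and cubic-spline correction of RR-interval series, a battery
    of 22 time-domain, frequency-domain (Burg autoregressive spectra) and
    nonlinear HRV measures (Poincare geometry, approximate and sample
    entropy, correlation dimension, detrended fluctuation analysis,
    recurrence quantification), robust multi-linear regression by
    iteratively reweighted least squares with Tukey bisquare weights, and
    exhaustive feature-subset selection under leave-one-subject-out
    cross-validation. A protocol-faithful synthetic-cohort generator with
    a known linear dependence of the pressure drop on HRV supports
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
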