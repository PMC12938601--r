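Package: erdica
Title: Independent Event-Related Brain Dynamics for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies motor-imagery EEG proficiency from independent
    event-related brain dynamics. Provides preprocessing of multichannel
    epoched EEG (EDF reading, FIR band-pass, artifact rejection), per-class
    Infomax independent component analysis, equivalent current dipole
    fitting in a concentric-sphere head model, spectral parameterization of
    component spectra into aperiodic and oscillatory parts, Morlet
    time-frequency maps with pseudo-T significance and connected-region
    summaries, a rule engine selecting contralateral ERD and ipsilateral
    ERS components, a Riemannian class-distinctiveness performance score,
    and two-stage k-means stratification of users into four proficiency
    groups, together with a forward-model synthetic-data generator used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
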