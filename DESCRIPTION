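Package: grfnet
Title: Three-Axis Ground Reaction Force Estimation from Plantar Load Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates three-axis ground reaction force (vertical,
    anterior-posterior, medial-lateral) during walking from three uniaxial
    plantar load cells placed under the heel and the first and fifth
    metatarsal heads. Provides signal preprocessing (resampling to a common
    200 Hz grid, zero-phase Butterworth lowpass filtering, heel-strike
    detection and instrument synchronization), a sequence-to-sequence LSTM
    regressor mapping the four load-cell input channels to the three force
    axes, a validation suite (per-axis correlation and RMSE, mid-stance
    timing error at the braking-to-propulsion transition, Bland-Altman
    agreement on peak forces), and a calibrated synthetic gait generator for
    end-to-end testing when laboratory force-plate data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
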