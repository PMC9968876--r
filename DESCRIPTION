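Package: imugrf
Title: Estimation of Vertical Ground Reaction Force Waveforms from
    Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Avery", "Collins", email = "avery.collins@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping inertial measurement unit (IMU) data
    recorded during overground running onto vertical ground reaction
    force (GRF) waveforms measured by force sensing insoles. Provides
    zero-lag Butterworth filtering and resampling, foot-stomp
    synchronization and iterative clock-drift correction between sensor
    timebases, assembly of fixed-length multi-channel training windows,
    a sequence-to-sequence LSTM regressor with hyperparameter search and
    leave-one-subject-out cross-validation, gait-event detection and
    kinetic variable extraction (contact time, stance average force,
    impulse, peak force, average loading rate), Bland-Altman and
    correlation agreement statistics, and a synthetic runner simulator
    with analytic ground truth so the full pipeline is testable without
    instrumented participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
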