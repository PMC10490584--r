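Package: cardioresp
Title: Combined Cardiac and Respiratory Monitoring from a Single Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts heartbeat times from a thoracic respiration
    (plethysmograph) signal via cardiogenic-oscillation enhancement
    (respiration-derived cardiogram, RDC), and reconstructs a composite
    respiration waveform from a single-lead ECG using R-peak amplitude
    modulation, R-R interval modulation and Q-trough depth modulation
    (ECG-derived respiration, EDR). Includes beat/breath event scoring
    against reference annotations, windowed heart-rate and
    respiration-rate agreement metrics (MAE, percentage error, NRMSE,
    Pearson and concordance correlation), sectioned best-lag waveform
    correlation, WFDB and CSV readers/writers, and a seeded generator of
    coupled synthetic ECG + respiration records with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
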