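Package: patcor
Title: Beat-by-Beat Pulse Arrival Time Extraction and Blood Pressure
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts beat-by-beat pulse arrival time (PAT) and pulse
    transit time (PTT) features from synchronized ECG, PPG, and arterial
    blood pressure (ABP) waveforms and evaluates their linear association
    with systolic, mean, and diastolic blood pressure. Provides zero-phase
    band-pass preprocessing, PPG derivative (VPG/APG) computation, fiducial
    point detection (ECG R peak; PPG pulse foot O, systolic peak S; VPG
    maximum-slope point w; APG a and b waves; ABP systolic peak S* and
    diastolic trough D*), automated signal-quality screening into
    missing/abnormal/good categories, and Pearson correlation analyses run
    subject by subject, on pooled beats, and on one best-quality beat per
    subject. A synthetic waveform generator with programmable, negative
    PAT-blood-pressure coupling supplies ground-truth-annotated records for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    withr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
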