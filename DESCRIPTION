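Package: polyscore
Title: Polyscore Cardiac Risk Stratification from Short Non-Invasive Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Polyscore, a composite cardiac risk score built from
    seven autonomic risk markers derived from simultaneous 30-minute recordings
    of high-frequency ECG, continuous arterial blood pressure and respiration:
    heart rate turbulence slope, deceleration capacity, baroreflex sensitivity,
    resting respiration rate, expiration-triggered sinus arrhythmia,
    post-ectopic potentiation of systolic blood pressure, and ectopic beat
    frequency. Each marker is dichotomized at an established cutoff and the
    Polyscore is the count of abnormal markers (0-7), mapped to low,
    intermediate and high risk classes. Includes automated beat detection and
    classification, phase-rectified signal averaging (univariate and
    bivariate), readers and writers for CSV, WFDB and EDF waveform files, a
    survival-analysis layer (Kaplan-Meier, log-rank, Cox models, per-stratum
    hazard ratios, log-rank cutoff optimization) for cohort validation, and a
    synthetic-recording and synthetic-cohort generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
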