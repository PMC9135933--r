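Package: cardiochron
Title: Comparative Cardiac-Aging Analysis for Rodent ECG, Echo and Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cross-sectional cardiac-aging studies in
    small rodents (laboratory mice and naked mole-rats). Implements R-peak
    detection and R-R series construction from multi-lead ECG, moving-average
    screening for irregular heartbeats, ensemble beat averaging with fiducial
    interval measurement (QRS, PR, PQ), rule-based premature-beat
    classification (atrial, ventricular, junctional), systolic and diastolic
    function metrics (stroke volume, ejection fraction, cardiac output,
    biplane atrial volume, transmitral E/A analysis), dobutamine
    stress-response deltas, and cross-sectional polynomial age-trend modelling
    with nested model selection. A synthetic-data module generates ECG
    recordings, Doppler inflow traces and cohort tables with known ground
    truth so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
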