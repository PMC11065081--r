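Package: beatvar
Title: Beat-to-Beat Blood Pressure Variability and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying very short-term (beat-to-beat) blood
    pressure variability (BPV) from continuous arterial pressure waveforms,
    and for assessing its intrasession test-retest reliability. Delineates
    systolic peaks and diastolic troughs from 100 Hz finger-cuff waveforms
    with automated artifact masking, computes dispersion (SD, CV, VIM),
    sequence (ARV) and instability (maximum minus minimum SBP) metrics
    alongside mean blood pressure and heart rate, and summarises paired
    test-retest sessions with paired t-tests, intraclass correlation
    coefficients with F-based confidence intervals and Munro grading,
    standard error of measurement, smallest real difference, Pearson
    correlation and Bland-Altman agreement, overall and stratified by
    antihypertensive medication use. Includes a seeded synthetic-cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
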