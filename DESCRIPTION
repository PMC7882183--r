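Package: cvrpipe
Title: Cerebrovascular Response to Exercise from Transcranial Doppler Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for computing the cerebrovascular response (CVR) to
    moderate-intensity exercise from beat-resolved transcranial Doppler
    middle cerebral artery velocity (MCAv) recordings. Includes cardiac-cycle
    segmentation, artifact censoring (implausible RR intervals, peak-velocity
    jumps) with a whole-acquisition discard rule, 2 Hz resampling with 3-s /
    9-s smoothing, resting and steady-state exercise MCAv windows, percent
    change in MCAv, Karvonen heart-rate prescriptions, exact Mann-Whitney U
    inference (tie-corrected z, recursive-counting exact null, permutation p),
    two-sided Fisher exact tests by point-probability summation, and a
    calibrated synthetic cohort generator with ground-truth recovery oracles
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
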