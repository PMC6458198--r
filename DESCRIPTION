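Package: theradose
Title: Dosimetry and Tumor-Response Analysis for Intratumoral PET
    Radiotracer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis pipeline for preclinical targeted
    radionuclide therapy delivered by intratumoral infusion of a
    positron-emitting radiotracer.  Extracts calibrated time-activity
    curves from 4D dynamic PET images and region-of-interest masks,
    computes decay-handled percent-injected-activity-per-gram curves,
    organ residence times and time-integrated activities (trapezoidal
    integration over the acquisition window plus an analytic
    physical-decay tail), calibrates the activity-to-dose conversion
    factor from Fricke dosimeter data, estimates absorbed doses, and
    scores tumor response from caliper growth curves (fivefold growth
    time, tumor growth delay, enhancement factor) with one-way ANOVA and
    Dunnett/Tukey multiple comparisons.  Includes seeded synthetic-data
    generators (time-activity curves, 4D phantoms, growth tables, Fricke
    calibration series) with known ground truth so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
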