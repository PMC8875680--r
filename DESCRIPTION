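Package: echogel
Title: Quantitative B-Mode Ultrasound Analysis of Aerogel Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing porous biomaterial
    (aerogel) implants in B-mode ultrasound images. Implements posterior
    acoustic shadow analysis (exponential intensity-decay fitting to obtain
    the attenuation coefficient in dB/cm), power-law calibration of the
    frequency dependence alpha = alpha0 * f^n, region-of-interest
    echogenicity quantification and classification
    (hyper-/iso-/hypo-/anechoic), and closed-form material acoustics
    (speed of sound, acoustic impedance, tissue impedance mismatch,
    pore-scattering attenuation). A calibrated speckle phantom generator
    with known ground truth makes every stage of the pipeline testable
    without access to device images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
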