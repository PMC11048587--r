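Package: kymovox
Title: Digital Kymography, Voice-Onset Metrics and Laryngeal Aerodynamics
    for High-Speed Laryngoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for vocal-fold vibration onset recorded by
    high-speed video laryngoscopy together with phonatory aerodynamic
    (PAS-style) traces. Extracts digital kymograms (DKG) from monochrome
    frame stacks, tracks left and right glottal edges to a subpixel
    vibrogram waveform, detects onset landmarks (adduction criterion,
    just-noticeable oscillation, steady state) and timing measures
    (pre-phonation time, cycles to steady state), performs FFT
    harmonic-peak analysis of the vibrogram, and derives per-token
    acoustic-aerodynamic measures (glottal resistance, resistance change
    per dB) with group summaries and a paired contrast of soft-to-modal
    versus modal-to-loud loudness transitions. A synthetic-data module
    generates seeded laryngoscopy frame stacks, kymograms and multichannel
    aerodynamic traces with known ground truth so every stage is testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
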