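Package: flexormod
Title: Two-Dimensional Musculoskeletal Model of Elbow-Flexor Hypertrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form two-dimensional model relating the anatomical
    cross-sectional area (ACSA) of the biceps brachii and brachialis to
    tendon line of action, moment-arm length, pennation angle, muscle and
    tendon force, and elbow-flexion moment contributions under uniform
    hypertrophy and atrophy scaling. Includes a hyperbolic-cosine ACSA
    profile object, a bounded least-squares profile fitter for
    position/ACSA measurement tables, a synthetic MRI-style sample
    generator, an alpha-sweep engine with tabular and graphical summaries,
    and a small command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
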