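Package: rotadapt
Title: Two-System Motor Learning Simulation for Visuomotor Rotation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three candidate architectures for motor skill learning and
    environment adaptation in block-design visuomotor rotation reaching experiments:
    a single shared basis-function network, one network per reaching target, and a
    two-system model with per-target task networks plus a single shared plant
    (environment) model trained on sensory prediction error. Includes the delayed
    proportional online feedback controller, Widrow-Hoff (LMS) learning for both
    systems, the standard baseline/interference/re-adaptation block protocols, the
    aftereffect z-score analysis of per-trial initial reach directions, and a
    phenomenological generator of human-like session data for validating the
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
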