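Package: gazedx
Title: Gaze-Based Best-Fit Diagnostic Algorithm for Autism Spectrum Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Constructs and validates an eye-tracking diagnostic classifier
    for autism spectrum disorder (ASD) in 5- to 17-year-olds from
    area-of-interest (AOI) gaze features. Implements AOI rate and count
    scoring of 50 Hz gaze recordings over a 12-clip social/preferential
    stimulus sequence, effect-size-driven candidate attribute selection with
    a gaze-fixation exclusion rule, a sigmoid-ensemble classifier built from
    four age-band by score-family sub-algorithms merged age-continuously into
    a single best-fit score, full leave-one-out cross-validation of the
    entire construction, external-cohort evaluation with ROC/AUC and
    Youden-index operating points, and a seeded Markov-chain gaze simulator
    for end-to-end testing with planted group differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
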