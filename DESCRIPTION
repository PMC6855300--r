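Package: emosift
Title: Semi-Automatic Extraction of Emotion-Labeled Frames from Prompt-Structured Game Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating emotion-labeled video frames from structured
    mobile game sessions in which a child acts out prompted emotions while
    being recorded. Session meta-information delimits the recording into
    prompt regions with known target emotions; frames are selected by region,
    trimmed by per-class leading (alpha) and trailing (beta) sub-bound
    intervals, and filtered by a per-class minimum classifier confidence
    (lambda), optionally fusing confidence scores from several emotion
    classification providers (min/max/average). Greedy per-class searches
    tune (alpha, beta, lambda) under a density-versus-yield tradeoff ratio,
    with an exhaustive grid oracle for verification. Includes consensus
    ground-truth construction from rater annotations with percent agreement
    and Cohen's kappa, and a seeded synthetic session and score generator so
    the whole pipeline is testable without video or cloud classifier access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
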