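Package: sstcoach
Title: Multimodal Feature Extraction and Normative Feedback for Automated
    Social Skills Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core of an automated social skills trainer for
    narrative skills. Extracts visual features from 66-point facial-landmark
    tracks (smiling ratio via a linear-kernel SVM over geometric face
    features, mean absolute yaw, signed mean pitch), prosodic features from
    mono audio (F0 variation in semitones, amplitude in dBFS, a jitter-like
    voice-quality index, pause ratio) and linguistic features from
    pre-tokenized transcripts (words per minute, long words, fillers).
    Turns a user's feature vector into normative feedback against a model
    cohort: per-feature z-scores, a 0-100 overall score from a linear
    regression model, and positive / needs-improvement comment selection.
    Drives the five-step training session (instruction, modeling,
    role-play, feedback, homework) as a testable state machine, provides
    the pre/post evaluation statistics (paired and two-sample one-tailed
    t-tests, pooled Cohen's d, Pearson correlation, above/below-mean rater
    agreement), and ships seeded synthetic-fixture generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
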