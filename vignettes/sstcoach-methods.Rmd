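---
title: "Methods: multimodal features and normative feedback for narrative-skill training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal features and normative feedback for narrative-skill training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstcoach)
```

## What the package models

Social skills training (SST) teaches social behaviors through five
canonical steps: instruction, modeling, role-playing, feedback, and
homework. An automated trainer replaces the human coach with a dialogue
agent: the user tells a positive story for one minute (the role-play), the
system measures audiovisual features of the telling, and the feedback step
shows how those features compare with a cohort of model speakers who tell
stories well. `sstcoach` implements the measurement and feedback core of
such a trainer plus the statistics used to evaluate it, with seeded
synthetic generators standing in for the camera, microphone and
transcription front-ends.

The target population includes children and young adults with autism
spectrum disorders, which shapes two design choices discussed below: the
reduced five-feature display, and coaching the *median* deviation rather
than the worst one.

## Visual features

The input is a 66-point facial-landmark track (one row per video frame,
pixel coordinates, plus head pose in degrees). Six geometric features are
computed per frame: outer and inner eyebrow height, outer and inner lip
height, eye opening, and lip-corner distance. Heights are mean vertical
distances between configured upper and lower landmark sets; the lip-corner
distance is Euclidean. All six are divided by the inter-ocular distance
(between the two eye-centroid points), which makes them invariant to
translation and uniform scale — necessary because recording distance is not
controlled.

The landmark-to-feature mapping is a *configuration*, not a fact about any
particular tracker: trackers disagree on indexing, so the default map
(`default_index_map()`, also shipped as `inst/extdata/index_map.yaml`)
documents one common 66-point annotation (17 jaw, 10 brow, 9 nose, 12 eye,
18 mouth points) and can be replaced wholesale. A smile model stores a hash
of the map it was trained under and refuses features from a different one.

**Smile classification.** A linear-kernel SVM (cost parameter defaulting to
1, features standardized by pooled training mean/sd) separates happy from
neutral feature vectors. Per frame, the decision value `w·z + b` is
thresholded at zero; *smiling requires strictly positive evidence*, so an
exact zero is labelled neutral. The smiling ratio is the proportion of
smiling frames with **no temporal smoothing** — it is a pure per-frame
count, so it equals k/n exactly for k smiling frames of n. Frames with
missing landmarks are excluded from numerator and denominator alike and
counted in the output, since tracker dropouts are routine.

**Head pose.** Yaw is summarized as the mean of absolute values (shift
from frontal, in degrees); pitch as the signed mean (positive = facing
down, negative = facing up), because looking down and looking up are
different behaviors and should not cancel against frontality the way
left/right turns do.

## Prosodic and linguistic features

The seven audio/linguistic features are named by the system design but
their operational definitions are this package's own, fixed in
`prosody_config()` and documented here:

* **F0** is estimated per 40 ms window (10 ms hop) by short-time
  autocorrelation with parabolic interpolation around the peak, searched
  in 75–500 Hz; a frame is voiced when its normalized autocorrelation peak
  is at least 0.5 and its level is above the silence threshold.
* **F0 variation** is the standard deviation of voiced-frame F0 in
  semitones (a log scale, so the measure is transposition-invariant).
* **Amplitude** is the mean frame RMS in dB relative to full scale over
  non-silent frames; halving the waveform lowers it by exactly
  20·log10(2) ≈ 6.02 dB.
* **Voice quality** is a jitter-like index: the mean absolute
  period-to-period change of the F0 period between *consecutive* voiced
  frames, relative to the mean period. Restricting to consecutive frames
  stops pauses from masquerading as perturbation. A steady tone scores ~0.
* **Pauses** are silent intervals (frame level below −35 dBFS) of at
  least 300 ms, reported as the fraction of the clip they occupy.

An all-silent clip leaves F0 variation, voice quality and amplitude as
explicit `NA` — undefined is never silently reported as zero.

Transcripts arrive pre-tokenized (the role-plays are Japanese; bundling a
morphological analyzer is out of scope). Words per minute is
`60·tokens/duration`; "words over six letters" counts tokens of character
length strictly greater than 6 (a literal reading of "over"); fillers are
exact lexicon matches after lower-casing, with a replaceable romanized
Japanese default lexicon (*eto*, *anou*, *maa*, ...).

## The feedback engine

Feedback has three parts.

**Z-scores.** Each feature is standardized against the model cohort's mean
and sd (n−1 denominator) and drawn on a radar chart against the cohort
baseline at z = 0. A zero cohort sd is an error naming the feature, never a
silent division.

**Overall score.** A Gaussian identity-link linear model (ordinary least
squares) predicts trainer-rated skill — rescaled from its Likert range to
0–100 — from four features: words per minute, amplitude, long words, and
smiling ratio. Predictions are clipped to [0, 100]. No canonical
coefficients exist to ship, so the model is fit on rated data by
`fit_score_model()`, which also reports the leave-one-out
cross-validated predicted-vs-observed Pearson correlation (computed in
closed form from the hat matrix; the tests verify it equals explicit
refits). Whether predictors are raw or standardized is a flag stored with
the model and reported by `glance()`; the default is raw, and prediction is
identical either way in exact arithmetic.

**Comments.** With distances `d = |z|`, the positive comment praises the
feature *closest* to the models (argmin). The needs-improvement comment
targets the feature at the *median* distance, not the farthest: for users
with social-communication difficulties, attacking the single worst feature
is often infeasible and demotivating, so the mid-ranked deviation is
coached instead. With distances sorted ascending, the improvement feature
sits at rank `floor((n+1)/2)` — the middle for odd n, the lower middle for
even n (an undefined case we had to fix by convention) — with a floor of
rank 2 so that with only two features the praised and coached features
still differ. Ties in distance break by canonical feature order, making the
selection independent of input order. Comment text is template-driven per
feature and per sign of z (English and romanized Japanese packs ship;
wording is replaceable, the selection policy is the contract).

Two feature presets exist: the full ten-feature set, and a reduced
five-feature set (pitch, words per minute, amplitude, long words, smiling
ratio) for younger users, where a ten-axis radar chart would overwhelm the
display.

## The session state machine

The five-step flow is an explicit transition table:
instruction →(start)→ modeling →(user_start_roleplay)→ roleplay
→(roleplay_timeout)→ feedback →(assign_homework)→ homework →(finish)→ done,
with `repeat` returning from feedback to modeling (default) or directly to
role-play, and `feedback_viewed` as a self-transition. The role-play exits
*only* on timeout at the configured duration (default 60 s). `advance()` is
a pure function of (state, event, config); illegal events raise an error
that names the step and the allowed events. The avatar, speech recognition
and rendering are replaced by this event interface — the state machine is
the testable contract. Nods are logged on a fixed 8 s schedule rather than
rendered. A feedback report can only be attached after a completed
role-play recording, making "report exists iff role-play completed" an
enforced invariant. Exhaustive enumeration of event sequences to depth 8
(in the tests and the acceptance script) confirms `done` is reachable only
through the five steps in order.

## Evaluation statistics

The pre/post evaluation uses:

* **Paired t** on `pre − post` (so improvement gives negative t), df = n−1.
  The one-tailed alternative for improvement is `less`; both one- and
  two-tailed p-values are always reported, because published analyses of
  this design sometimes label one while printing the other, and surfacing
  both avoids adjudicating.
* **Two-sample pooled-variance Student's t**, df = n₁+n₂−2, for group
  comparisons.
* **Cohen's d** in the pooled-sd-of-two-groups convention,
  `d = (mean(post) − mean(pre)) / sqrt((var(pre)+var(post))/2)` — not the
  d-of-differences, which yields a different number for the same data. The
  bundled ten-participant rating table (`asd_ratings()`) gives t(9) = −4
  exactly (mean difference 1.6, sd of differences √1.6) and d = 1.17 at two
  decimals.
* **Pearson correlation** for skill-vs-skill relationships.
* **Above/below-mean rater agreement**: each rater's scores are binarized
  against that rater's own mean (ties at the mean class as "high", a
  convention we fixed) and agreement is the fraction of matching classes.

```{r table1}
evaluate_ratings(asd_ratings())$summary
```

## Synthetic fixtures and what they do (and do not) show

Every pipeline stage is testable offline against generators with known
ground truth, all pure functions of (spec, seed):

* `gen_landmark_track()` interpolates between constructed neutral/happy
  templates on contiguous smile episodes totalling a requested fraction of
  frames (episode gaps drawn randomly, so any fraction is feasible), with
  Gaussian landmark jitter and random-walk head pose around configurable
  offsets. The templates are built geometry — raised, widened lip corners,
  lifted brows, narrowed eyes — not a face database.
* `gen_smile_training_features()` draws class clusters around the two
  templates' feature centroids with per-feature sd `|Δ|/shift`, so `shift`
  is the class separation in training-sd units (default 3). The default
  sample sizes (31 happy, 30 neutral) mirror a small expression-database
  training set.
* `gen_audio()` produces a harmonic tone with slow seeded F0 modulation,
  scheduled digital silences and a target RMS level; truth pause ratio and
  F0 follow analytically from the spec.
* `gen_cohort()` / `gen_ratings()` draw model-speaker features from
  independent normals with plausible one-minute-narrative defaults
  (e.g. ~120 words/min, smiling ratio ~0.35, amplitude ~−22 dBFS) and
  ratings as a declared linear combination plus noise, returning the
  generating weights.

Passing recovery tests on these fixtures shows the *computational* chain is
correct: geometry to features, features to classification, counts to
ratios, schedules to pause ratios, weights to fits. It does not show that
real smiles separate this cleanly, that real F0 tracks are this stable, or
that trainer ratings are linear in four features — real landmark tracks
have correlated, non-Gaussian error, real speech has breathy/creaky
segments that defeat autocorrelation pitch tracking, and real raters drift.
The recovery tolerances (smile fraction to ±0.02 on 600-frame tracks,
pause ratio to within a frame hop) are claims about the implementation
under the generator's assumptions, not about field accuracy.

## Numerical choices and degenerate inputs

* SVM decision ties (exactly 0) → neutral; orientation is fixed after
  fitting so the happy centroid's decision value is positive.
* Constant training features: error by default, or drop-with-warning
  (weight pinned to 0) by configuration; identical happy/neutral sets are
  a degenerate-training error.
* Zero inter-ocular distance is an error (a collapsed face, not data).
* Zero cohort sd, zero variance of paired differences, zero pooled
  variance, constant correlation inputs: all errors naming the cause.
* Rank-deficient score designs are rejected rather than silently dropped.
* Pose units are degrees end to end; radians convert at read time.
* The F0 search range (75–500 Hz), silence threshold (−35 dBFS), minimum
  pause (300 ms) and voicing threshold (0.5) are config values; their
  defaults suit clean close-microphone speech surrogates.

## Problem sizes

The test and acceptance runs use one-minute tracks at 10 fps (600 frames),
10 s audio at 16 kHz, cohorts of 20–30 model speakers with 200 for the
asymptotic cross-validation check, and 20 seeds for the recovery sweeps —
sizes chosen to exercise every code path at interactive speed while keeping
the statistical checks well-powered.

## Known limitations

* The prosodic definitions are reproducible substitutes, not a reimplementation
  of any published feature extractor; absolute values are not comparable
  across toolchains, only within this one.
* Whether "words over six letters" should count Japanese characters, morae
  or romanized letters is genuinely ambiguous; we count characters of the
  tokens as delivered.
* The smile classifier's accuracy on real faces depends entirely on the
  training exemplars supplied; the shipped synthetic clusters only
  validate the machinery.
* Group-level results that depend on unpublished per-subject ratings
  (rater-agreement percentages, correlation tables against external
  skill categories, the original cross-validated r) cannot be reproduced;
  the operations are implemented and property-tested instead.
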