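#' Narrative feature presets
#'
#' The feedback engine works over a named feature set in a canonical order
#' (the order also breaks ties in comment selection). Two presets are
#' available:
#'
#' * `"full"` — the ten-feature set: three visual (smiling ratio, mean
#'   absolute yaw, signed mean pitch) and seven audio/linguistic (F0
#'   variation, amplitude, voice quality, pause ratio, words per minute,
#'   long words, fillers).
#' * `"asd5"` — the reduced five-feature set used with younger users so the
#'   display stays legible: pitch, words per minute, amplitude, long words,
#'   and smiling ratio.
#'
#' @param preset `"full"` or `"asd5"`.
#' @return Character vector of feature names in canonical order.
#' @export
#' @examples
#' feature_preset("asd5")
feature_preset <- function(preset = c("full", "asd5")) {
  preset <- match.arg(preset)
  switch(preset,
    full = c("smiling_ratio", "yaw_abs_mean", "pitch_mean",
             "f0_variation", "amplitude", "voice_quality", "pause_ratio",
             "words_per_minute", "long_word_count", "filler_count"),
    asd5 = c("pitch_mean", "words_per_minute", "amplitude",
             "long_word_count", "smiling_ratio")
  )
}

#' Features entering the overall-score regression
#'
#' The overall 0-100 score is predicted from the statistically informative
#' subset: words per minute, amplitude, words over six letters, and smiling
#' ratio.
#' @return Character vector of four feature names.
#' @export
score_feature_names <- function() {
  c("words_per_minute", "amplitude", "long_word_count", "smiling_ratio")
}

#' Extract the full narrative feature vector for one role-play
#'
#' Runs the visual, prosodic and linguistic extractors and binds the result
#' into a single one-row tibble — the per-session feature vector consumed by
#' the feedback engine.
#'
#' @param track Landmark-track tibble ([as_landmark_track()]).
#' @param smile_model A [train_smile_model()] model.
#' @param clip An [audio_clip()].
#' @param tr A [transcript()].
#' @param index_map See [default_index_map()].
#' @param prosody_cfg See [prosody_config()].
#' @return A one-row tibble with the ten `"full"`-preset features.
#' @export
extract_narrative_features <- function(track, smile_model, clip, tr,
                                       index_map = default_index_map(),
                                       prosody_cfg = prosody_config()) {
  sm <- smiling_ratio(track, smile_model, index_map)
  hp <- head_pose_summary(track)
  pr <- extract_prosody(clip, prosody_cfg)
  lg <- extract_linguistic(tr)
  tibble::tibble(
    smiling_ratio = sm$smiling_ratio,
    yaw_abs_mean = hp$yaw_abs_mean,
    pitch_mean = hp$pitch_mean,
    f0_variation = pr$f0_variation,
    amplitude = pr$amplitude,
    voice_quality = pr$voice_quality,
    pause_ratio = pr$pause_ratio
  ) |>
    dplyr::bind_cols(lg)
}
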