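#' Session configuration
#'
#' @param roleplay_duration_s Role-play length in seconds (default 60, the
#'   one-minute monologue).
#' @param allow_repeats Whether the `repeat` event is accepted from the
#'   feedback step (users typically repeat modeling and role-play several
#'   times).
#' @param repeat_to Where `repeat` returns to: `"modeling"` (default, watch
#'   the model video again) or `"roleplay"` (retry immediately).
#' @param nod_interval_s Interval of the avatar's logged nod events during
#'   role-play (default 8 s).
#' @param prompts Named list of system utterances; defaults include the
#'   role-play elicitation prompt.
#' @param model_videos Character vector of model-video references shown in
#'   the modeling step.
#' @return A list of class `session_config`.
#' @export
session_config <- function(roleplay_duration_s = 60, allow_repeats = TRUE,
                           repeat_to = c("modeling", "roleplay"),
                           nod_interval_s = 8,
                           prompts = list(
                             roleplay = "please describe something fun you did recently",
                             homework = "tell a story to others throughout the week"
                           ),
                           model_videos = character()) {
  if (roleplay_duration_s <= 0) abort("roleplay_duration_s must be > 0")
  structure(list(roleplay_duration_s = roleplay_duration_s,
                 allow_repeats = allow_repeats,
                 repeat_to = match.arg(repeat_to),
                 nod_interval_s = nod_interval_s,
                 prompts = prompts, model_videos = model_videos),
            class = "session_config")
}

#' Session steps and events
#'
#' The training session is an explicit state machine over the five
#' canonical steps — instruction, modeling, role-playing, feedback,
#' homework — plus a terminal `done` state.
#' @return Character vectors of the step and event names.
#' @export
session_steps <- function() {
  c("instruction", "modeling", "roleplay", "feedback", "homework", "done")
}

#' @rdname session_steps
#' @export
session_events <- function() {
  c("start", "user_start_roleplay", "roleplay_timeout", "feedback_viewed",
    "repeat", "assign_homework", "finish")
}

# transition table: role-play exits only on timeout; repeat only from feedback
session_transitions <- function(config) {
  tbl <- tibble::tribble(
    ~step,         ~event,                 ~to,
    "instruction", "start",                "modeling",
    "modeling",    "user_start_roleplay",  "roleplay",
    "roleplay",    "roleplay_timeout",     "feedback",
    "feedback",    "feedback_viewed",      "feedback",
    "feedback",    "assign_homework",      "homework",
    "homework",    "finish",               "done"
  )
  if (config$allow_repeats) {
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(
      step = "feedback", event = "repeat", to = config$repeat_to))
  }
  tbl
}

#' Create a new training session
#'
#' @param config A [session_config()].
#' @return An object of class `sst_session` starting in the `instruction`
#'   step with an empty log and no artifacts.
#' @export
new_session <- function(config = session_config()) {
  structure(
    list(step = "instruction", elapsed_s = 0,
         repeats = stats::setNames(rep(0L, 6), session_steps()),
         artifacts = list(), reports = list(), log = list(),
         config = config),
    class = "sst_session"
  )
}

#' @export
print.sst_session <- function(x, ...) {
  cat("<sst_session> step:", x$step,
      "| roleplays completed:", n_completed_roleplays(x),
      "| reports:", length(x$reports), "\n")
  invisible(x)
}

n_completed_roleplays <- function(session) {
  sum(vapply(session$artifacts,
             function(a) identical(a$kind, "roleplay_recording") && isTRUE(a$completed),
             logical(1)))
}

#' Advance the session state machine
#'
#' Applies one event to the session. `advance()` is a pure function of
#' (state, event, config): illegal events are rejected with an explanation
#' and leave the state untouched (an error is raised). The role-play step
#' exits only through `roleplay_timeout`; every path to `done` passes the
#' five steps in order, with repeats allowed only via the feedback step.
#'
#' @param session An `sst_session`.
#' @param event One of [session_events()].
#' @param at Event timestamp in seconds (monotone within a session); used
#'   only for the log.
#' @return The updated `sst_session`.
#' @export
#' @examples
#' s <- new_session()
#' s <- advance(s, "start")
#' s$step
advance <- function(session, event, at = NA_real_) {
  stopifnot(inherits(session, "sst_session"))
  if (!event %in% session_events()) {
    abort(paste0("unknown event `", event, "`"))
  }
  tbl <- session_transitions(session$config)
  row <- tbl[tbl$step == session$step & tbl$event == event, ]
  if (nrow(row) == 0) {
    allowed <- tbl$event[tbl$step == session$step]
    abort(paste0("event `", event, "` is not allowed in step `", session$step,
                 "`; allowed: ", paste(unique(allowed), collapse = ", ")))
  }
  to <- row$to[[1]]
  session$log <- c(session$log, list(list(
    time = at, step = session$step, event = event, to = to)))
  if (to == session$step || match(to, session_steps()) < match(session$step, session_steps())) {
    session$repeats[[to]] <- session$repeats[[to]] + 1L
  }
  session$step <- to
  session$elapsed_s <- 0
  session
}

#' Run (simulate) the timed role-play recording
#'
#' Marks the role-play recording over the configured duration: start/stop
#' timestamps, the nod-event schedule (the avatar nods at a fixed interval
#' while the user talks), and references to the captured landmark CSV,
#' WAV and transcript handed to the extractors. The session must currently
#' be in the `roleplay` step. The recording artifact is appended to the
#' session; the state itself still advances only via the
#' `roleplay_timeout` event.
#'
#' @param session An `sst_session` in step `roleplay`.
#' @param clock A function returning the current time in seconds (injected
#'   for testability; default starts at 0).
#' @param landmarks,wav,transcript Paths or references to the captured
#'   inputs (carried, not read here).
#' @return The session with the completed recording artifact appended; the
#'   artifact itself is in `$artifacts`.
#' @export
run_roleplay <- function(session, clock = function() 0,
                         landmarks = NULL, wav = NULL, transcript = NULL) {
  stopifnot(inherits(session, "sst_session"))
  if (session$step != "roleplay") {
    abort(paste0("role-play can only run in step `roleplay` (currently `",
                 session$step, "`)"))
  }
  start <- clock()
  dur <- session$config$roleplay_duration_s
  nods <- seq(0, dur, by = session$config$nod_interval_s)[-1]
  artifact <- list(kind = "roleplay_recording", start = start,
                   stop = start + dur, duration_s = dur,
                   nod_times = start + nods,
                   landmarks = landmarks, wav = wav, transcript = transcript,
                   completed = TRUE)
  session$artifacts <- c(session$artifacts, list(artifact))
  session$log <- c(session$log, list(list(
    time = start, step = "roleplay", event = "recording_completed", to = "roleplay")))
  session
}

#' Attach a feedback report to a session
#'
#' A report may exist only for a completed role-play: attaching without one
#' is rejected, which makes "report exists iff a role-play completed" an
#' enforced invariant rather than a convention.
#'
#' @param session An `sst_session`.
#' @param report An `sst_feedback`.
#' @return The session with the report appended.
#' @export
attach_report <- function(session, report) {
  stopifnot(inherits(session, "sst_session"), inherits(report, "sst_feedback"))
  if (n_completed_roleplays(session) <= length(session$reports)) {
    abort("no completed role-play without a report; cannot attach feedback")
  }
  session$reports <- c(session$reports, list(report))
  session$log <- c(session$log, list(list(
    time = NA_real_, step = session$step, event = "report_attached",
    to = session$step)))
  session
}

#' Write the session log as JSON lines
#'
#' One event per line: timestamp, step, event, resulting step.
#'
#' @param session An `sst_session`.
#' @param path Output path.
#' @export
write_session_log <- function(session, path) {
  lines <- vapply(session$log, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Run a scripted offline session over pre-recorded inputs
#'
#' Drives the five-step flow end to end on captured files: instruction,
#' modeling, the timed role-play over the supplied landmark track / audio /
#' transcript, feature extraction and feedback, homework. Returns the
#' finished session together with the extracted features and the feedback
#' report.
#'
#' @param track Landmark-track tibble.
#' @param clip An [audio_clip()].
#' @param tr A [transcript()].
#' @param smile_model A `smile_model`.
#' @param cohort Model-cohort feature data frame.
#' @param score_model Score model for [predict_overall_score()].
#' @param config A [session_config()].
#' @param features Active feature preset for the report.
#' @param templates Comment templates.
#' @return A list: `session` (`sst_session`, in step `done`), `features`
#'   (one-row tibble), `report` (`sst_feedback`).
#' @export
run_session <- function(track, clip, tr, smile_model, cohort, score_model,
                        config = session_config(),
                        features = feature_preset("asd5"),
                        templates = default_comment_templates()) {
  s <- new_session(config)
  s <- advance(s, "start", at = 0)
  s <- advance(s, "user_start_roleplay", at = 0)
  s <- run_roleplay(s, landmarks = "track", wav = "clip", transcript = "transcript")
  s <- advance(s, "roleplay_timeout", at = config$roleplay_duration_s)
  feats <- extract_narrative_features(track, smile_model, clip, tr)
  report <- build_feedback(feats, cohort, score_model,
                           templates = templates, features = features)
  s <- attach_report(s, report)
  s <- advance(s, "feedback_viewed", at = config$roleplay_duration_s)
  s <- advance(s, "assign_homework", at = config$roleplay_duration_s)
  s <- advance(s, "finish", at = config$roleplay_duration_s)
  list(session = s, features = feats, report = report)
}
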