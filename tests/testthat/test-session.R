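test_that("the happy path traverses the five steps in order", {
  s <- new_session()
  expect_equal(s$step, "instruction")
  s <- advance(s, "start")
  expect_equal(s$step, "modeling")
  s <- advance(s, "user_start_roleplay")
  expect_equal(s$step, "roleplay")
  s <- advance(s, "roleplay_timeout")
  expect_equal(s$step, "feedback")
  s <- advance(s, "assign_homework")
  expect_equal(s$step, "homework")
  s <- advance(s, "finish")
  expect_equal(s$step, "done")
  visited <- vapply(s$log, `[[`, character(1), "step")
  expect_equal(visited,
               c("instruction", "modeling", "roleplay", "feedback", "homework"))
})

test_that("illegal events are rejected with the state untouched", {
  s <- advance(advance(new_session(), "start"), "user_start_roleplay")
  expect_equal(s$step, "roleplay")
  expect_error(advance(s, "feedback_viewed"), "not allowed")
  expect_error(advance(s, "finish"), "not allowed")
  expect_equal(s$step, "roleplay")   # rejection left the object as-is
  expect_error(advance(s, "no_such_event"), "unknown event")

  no_repeat <- new_session(session_config(allow_repeats = FALSE))
  no_repeat$step <- "feedback"
  expect_error(advance(no_repeat, "repeat"), "not allowed")
})

test_that("repeat returns from feedback to modeling or role-play", {
  to_feedback <- function(cfg) {
    s <- new_session(cfg)
    s <- advance(s, "start")
    s <- advance(s, "user_start_roleplay")
    advance(s, "roleplay_timeout")
  }
  s1 <- advance(to_feedback(session_config()), "repeat")
  expect_equal(s1$step, "modeling")
  s2 <- advance(to_feedback(session_config(repeat_to = "roleplay")), "repeat")
  expect_equal(s2$step, "roleplay")
})

test_that("advance is a pure function of state, event and config", {
  s <- advance(new_session(), "start")
  a <- advance(s, "user_start_roleplay", at = 1)
  b <- advance(s, "user_start_roleplay", at = 1)
  expect_identical(a, b)
})

test_that("role-play recording spans the configured duration and logs nods", {
  mk <- function(dur) {
    s <- new_session(session_config(roleplay_duration_s = dur))
    s <- advance(s, "start")
    advance(s, "user_start_roleplay")
  }
  s60 <- run_roleplay(mk(60), clock = function() 100)
  art <- s60$artifacts[[1]]
  expect_equal(art$stop - art$start, 60)
  expect_equal(art$nod_times, 100 + seq(8, 60, by = 8))

  s30 <- run_roleplay(mk(30), clock = function() 0)
  expect_equal(s30$artifacts[[1]]$duration_s, 30)

  # outside the role-play step the recording is refused, state preserved
  s <- advance(new_session(), "start")
  expect_error(run_roleplay(s), "roleplay")
  expect_equal(s$step, "modeling")
  expect_length(s$artifacts, 0)
})

test_that("a feedback report requires a completed role-play", {
  cohort <- gen_cohort(n_models = 10, seed = 41)
  zero_model <- list(intercept = 50,
                     coef = list(words_per_minute = 0, amplitude = 0,
                                 long_word_count = 0, smiling_ratio = 0))
  fb <- build_feedback(cohort[1, ], cohort, zero_model)
  s <- advance(new_session(), "start")
  expect_error(attach_report(s, fb), "role-play")
  s <- advance(s, "user_start_roleplay")
  s <- run_roleplay(s)
  s <- attach_report(s, fb)
  expect_length(s$reports, 1)
  expect_error(attach_report(s, fb), "role-play")  # one report per recording
})

test_that("an exhaustive event enumeration reaches done only via the five steps", {
  events <- session_events()
  ordered <- c("instruction", "modeling", "roleplay", "feedback", "homework")
  paths_to_done <- 0L
  explore <- function(session, steps_seen, depth) {
    for (ev in events) {
      nxt <- tryCatch(advance(session, ev), error = function(e) NULL)
      if (is.null(nxt)) next
      seen <- c(steps_seen, nxt$step)
      if (nxt$step == "done") {
        paths_to_done <<- paths_to_done + 1L
        # forward progress must visit the five steps in order, first to last
        firsts <- vapply(c(ordered, "done"), function(st) match(st, seen),
                         numeric(1))
        expect_false(anyNA(firsts))
        expect_true(all(diff(firsts) > 0))
        # instruction, homework and done are never repeated
        counts <- table(seen)
        expect_true(all(counts[intersect(names(counts),
                                         c("instruction", "homework", "done"))] == 1))
      } else if (depth > 1) {
        explore(nxt, seen, depth - 1)
      }
    }
  }
  s0 <- new_session()
  explore(s0, "instruction", 8)
  expect_gt(paths_to_done, 0)
})

test_that("the scripted offline session produces features, report and log", {
  m <- fixture_smile_model()
  g <- gen_landmark_track(track_spec(duration_s = 6, fps = 10,
                                     smile_fraction = 0.5), seed = 42)
  ga <- gen_audio(audio_spec(duration_s = 6, pauses = list(c(2, 0.5))), seed = 43)
  tr <- transcript(c(rep("tanoshii", 10), "eto"), duration_s = 6)
  cohort <- gen_cohort(n_models = 15, seed = 44)
  gr <- gen_ratings(cohort, noise_sd = 3, seed = 45)
  sm <- fit_score_model(cohort, gr$ratings, rating_scale = c(0, 100))

  res <- run_session(g$track, ga$clip, tr, m, cohort, sm,
                     config = session_config(roleplay_duration_s = 6))
  expect_equal(res$session$step, "done")
  expect_length(res$session$reports, 1)
  expect_equal(res$features$smiling_ratio, 0.5, tolerance = 0.02)
  expect_true(res$report$overall_score >= 0 && res$report$overall_score <= 100)

  log_path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(res$session, log_path)
  lines <- readLines(log_path)
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_true(all(vapply(parsed, function(e) is.character(e$event), logical(1))))
  expect_true(any(vapply(parsed, function(e) e$event == "recording_completed",
                         logical(1))))
})
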