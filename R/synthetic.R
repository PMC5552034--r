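#' Constructed neutral and happy landmark templates
#'
#' Two 66-point landmark configurations built from simple face geometry
#' (eyes 40 px apart, jaw oval, elliptical lips). The happy template raises
#' and widens the lip corners, opens the mouth slightly, lifts the brows
#' and narrows the eyes relative to neutral — the displacement pattern a
#' smile produces in the six geometric features. The templates are
#' synthetic constructions for testing and simulation, not derived from
#' any face database.
#'
#' @return A list with `neutral` and `happy`, each a 66 x 2 matrix of
#'   (x, y) pixel coordinates (rows = 0-based landmark index + 1).
#' @export
landmark_templates <- function() {
  pts <- matrix(NA_real_, 66, 2)
  # jaw 0-16: lower face oval, ear to ear through the chin
  a <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, ] <- cbind(100 + 40 * cos(a), 95 - 50 * sin(a))
  # brows 17-21 / 22-26: gentle arcs above the eyes
  bx <- seq(65, 92, length.out = 5)
  pts[18:22, ] <- cbind(bx, 72 - 3 * sin(seq(0, pi, length.out = 5)))
  pts[23:27, ] <- cbind(bx + 43, 72 - 3 * sin(seq(0, pi, length.out = 5)))
  # nose 27-30 bridge, 31-35 base
  pts[28:31, ] <- cbind(rep(100, 4), c(80, 87, 94, 100))
  pts[32:36, ] <- cbind(seq(92, 108, length.out = 5), rep(105, 5))
  # eyes 36-41 / 42-47: hexagons centred (80, 82) and (120, 82)
  eye <- function(cx) {
    cbind(cx + c(-10, -4, 4, 10, 4, -4), 82 + c(0, -3, -3, 0, 3, 3))
  }
  pts[37:42, ] <- eye(80)
  pts[43:48, ] <- eye(120)
  # mouth: outer lip 48-59 (corner, top, corner, bottom), inner lip 60-65
  oa <- seq(180, -150, by = -30) * pi / 180
  pts[49:60, ] <- cbind(100 + 18 * cos(oa), 128 - 9 * sin(oa))
  ia <- c(150, 90, 30, -30, -90, -150) * pi / 180
  pts[61:66, ] <- cbind(100 + 13 * cos(ia), 128 - 4 * sin(ia))

  neutral <- pts
  happy <- pts
  corner_rows <- c(49, 55)            # outer corners (indices 48, 54)
  happy[corner_rows, 1] <- happy[corner_rows, 1] + c(-4, 4)
  happy[corner_rows, 2] <- happy[corner_rows, 2] - 7
  near_corner <- c(50, 54, 56, 60)    # indices 49, 53, 55, 59
  happy[near_corner, 2] <- happy[near_corner, 2] - 3
  happy[57:59, 2] <- happy[57:59, 2] + 3    # lower outer lip drops: mouth opens
  happy[64:66, 2] <- happy[64:66, 2] + 3    # lower inner lip likewise
  happy[18:27, 2] <- happy[18:27, 2] - 2    # brows lift
  lid_rows <- c(38, 39, 44, 45)             # upper lids (37, 38, 43, 44)
  happy[lid_rows, 2] <- happy[lid_rows, 2] + 1  # eyes narrow

  list(neutral = neutral, happy = happy)
}

#' Build a constant landmark track from a template
#'
#' @param template 66 x 2 coordinate matrix (see [landmark_templates()]).
#' @param n_frames Number of identical frames.
#' @param fps Frames per second.
#' @param yaw,pitch,roll Constant pose values in degrees.
#' @return A landmark-track tibble.
#' @export
template_track <- function(template, n_frames = 1, fps = 10,
                           yaw = 0, pitch = 0, roll = 0) {
  stopifnot(nrow(template) == 66, ncol(template) == 2)
  out <- tibble::tibble(frame = seq_len(n_frames) - 1L,
                        t = (seq_len(n_frames) - 1L) / fps)
  for (i in 0:65) out[[paste0("x", i)]] <- template[i + 1, 1]
  for (i in 0:65) out[[paste0("y", i)]] <- template[i + 1, 2]
  out$yaw <- yaw; out$pitch <- pitch; out$roll <- roll
  as_landmark_track(out)
}

#' Generate seeded smile-classifier training features
#'
#' Draws happy and neutral face-feature vectors around the feature-space
#' centroids of the constructed templates. The per-feature class standard
#' deviation is `|happy - neutral| / shift` (with a small floor for
#' features the smile barely moves), so `shift` is the class separation in
#' training-sd units: `shift = 3` gives well-separated but overlapping
#' clusters. The default sample sizes mirror a small expression-database
#' training set (31 happy, 30 neutral).
#'
#' @param n_happy,n_neutral Samples per class.
#' @param shift Separation between class centroids in within-class sd
#'   units.
#' @param seed Integer seed; generation is a pure function of the
#'   arguments.
#' @param index_map See [default_index_map()].
#' @return A tibble of the six face features plus a `label` column
#'   (`"happy"` / `"neutral"`).
#' @export
gen_smile_training_features <- function(n_happy = 31, n_neutral = 30,
                                        shift = 3, seed = 1,
                                        index_map = default_index_map()) {
  stopifnot(n_happy >= 1, n_neutral >= 1, shift > 0)
  tpl <- landmark_templates()
  feats <- face_feature_names()
  cn <- as.numeric(face_features(template_track(tpl$neutral), index_map)[1, feats])
  ch <- as.numeric(face_features(template_track(tpl$happy), index_map)[1, feats])
  sds <- pmax(abs(ch - cn), 0.02) / shift
  rng <- local_seed(seed)
  draw <- function(centroid, n, label) {
    m <- matrix(rng$rnorm(n * 6), n, 6)
    m <- sweep(sweep(m, 2, sds, "*"), 2, centroid, "+")
    m <- abs(m)  # geometric lengths are non-negative
    out <- tibble::as_tibble(as.data.frame(m))
    names(out) <- feats
    out$label <- label
    out
  }
  dplyr::bind_rows(draw(ch, n_happy, "happy"), draw(cn, n_neutral, "neutral"))
}

#' Track generation spec
#'
#' @param duration_s Track length in seconds (default 60, one role-play).
#' @param fps Frames per second (default 10).
#' @param smile_fraction Target fraction of smiling frames in \[0, 1\].
#' @param n_episodes Number of contiguous smile episodes the smiling frames
#'   are split into (smiles come in blocks, not i.i.d. frames).
#' @param noise_px Landmark jitter sd in pixels per coordinate.
#' @param yaw_offset,pitch_offset Mean head-pose offsets in degrees.
#' @param yaw_walk_sd,pitch_walk_sd Random-walk step sd (degrees/frame).
#' @return A list of class `track_spec`.
#' @export
track_spec <- function(duration_s = 60, fps = 10, smile_fraction = 0.3,
                       n_episodes = 3, noise_px = 0.3,
                       yaw_offset = 0, pitch_offset = 0,
                       yaw_walk_sd = 0.5, pitch_walk_sd = 0.5) {
  stopifnot(duration_s > 0, fps > 0,
            smile_fraction >= 0, smile_fraction <= 1,
            n_episodes >= 1, noise_px >= 0,
            yaw_walk_sd >= 0, pitch_walk_sd >= 0)
  structure(list(duration_s = duration_s, fps = fps,
                 smile_fraction = smile_fraction, n_episodes = n_episodes,
                 noise_px = noise_px,
                 yaw_offset = yaw_offset, pitch_offset = pitch_offset,
                 yaw_walk_sd = yaw_walk_sd, pitch_walk_sd = pitch_walk_sd),
            class = "track_spec")
}

#' Generate a landmark track with known smile episodes and pose wander
#'
#' Frames are the neutral template, switched to the happy template on
#' contiguous smile episodes whose total length is
#' `round(smile_fraction * n_frames)` frames, plus Gaussian landmark
#' jitter. Episode placement draws the gaps between episodes uniformly at
#' random (seeded), so any reachable fraction is feasible. Yaw and pitch
#' follow seeded random walks around their offsets. The generator is a
#' pure function of (spec, seed); the per-frame smile mask is returned as
#' ground truth.
#'
#' @param spec A [track_spec()].
#' @param seed Integer seed.
#' @param templates See [landmark_templates()].
#' @return A list: `track` (landmark-track tibble), `truth` (logical
#'   per-frame smile mask), `n_smile_frames`.
#' @export
gen_landmark_track <- function(spec = track_spec(), seed = 1,
                               templates = landmark_templates()) {
  stopifnot(inherits(spec, "track_spec"))
  n <- round(spec$duration_s * spec$fps)
  if (n < 1) abort("spec yields an empty track")
  k <- round(spec$smile_fraction * n)
  n_ep <- if (k == 0) 0L else min(spec$n_episodes, k)
  if (k > n) abort("smile_fraction unreachable: more smile frames than frames")
  rng <- local_seed(seed)

  mask <- rep(FALSE, n)
  if (n_ep > 0) {
    lens <- rep(k %/% n_ep, n_ep)
    extra <- k %% n_ep
    if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
    free <- n - k
    cuts <- sort(rng$runif(n_ep)) * free
    gaps <- diff(c(0, floor(cuts)))
    pos <- 1L
    for (i in seq_len(n_ep)) {
      pos <- pos + gaps[i]
      mask[pos:(pos + lens[i] - 1L)] <- TRUE
      pos <- pos + lens[i]
    }
  }

  nxy <- templates$neutral; hxy <- templates$happy
  xs <- matrix(rep(nxy[, 1], each = n), n, 66)
  ys <- matrix(rep(nxy[, 2], each = n), n, 66)
  if (any(mask)) {
    xs[mask, ] <- matrix(rep(hxy[, 1], each = sum(mask)), sum(mask), 66)
    ys[mask, ] <- matrix(rep(hxy[, 2], each = sum(mask)), sum(mask), 66)
  }
  if (spec$noise_px > 0) {
    xs <- xs + matrix(rng$rnorm(n * 66, sd = spec$noise_px), n, 66)
    ys <- ys + matrix(rng$rnorm(n * 66, sd = spec$noise_px), n, 66)
  }
  yaw <- spec$yaw_offset + cumsum(rng$rnorm(n, sd = spec$yaw_walk_sd))
  pitch <- spec$pitch_offset + cumsum(rng$rnorm(n, sd = spec$pitch_walk_sd))

  track <- tibble::tibble(frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / spec$fps)
  for (i in 0:65) track[[paste0("x", i)]] <- xs[, i + 1]
  for (i in 0:65) track[[paste0("y", i)]] <- ys[, i + 1]
  track$yaw <- yaw; track$pitch <- pitch; track$roll <- 0
  list(track = as_landmark_track(track), truth = mask, n_smile_frames = k)
}

#' Audio generation spec
#'
#' @param duration_s Clip length, seconds.
#' @param sample_rate Hz.
#' @param f0_hz Base fundamental frequency.
#' @param f0_jitter_hz Sd of the slow (10 ms control grid) F0 modulation;
#'   0 gives a perfectly steady tone.
#' @param amplitude_db Target RMS level of the voiced part, dBFS.
#' @param n_harmonics Harmonics in the speech-surrogate tone.
#' @param pauses List of `c(onset_s, length_s)` silent intervals; must lie
#'   within the clip and not overlap.
#' @return A list of class `audio_spec`.
#' @export
audio_spec <- function(duration_s = 10, sample_rate = 16000, f0_hz = 220,
                       f0_jitter_hz = 0, amplitude_db = -20, n_harmonics = 3,
                       pauses = list()) {
  stopifnot(duration_s > 0, sample_rate > 0, f0_hz > 0, f0_jitter_hz >= 0,
            n_harmonics >= 1)
  if (length(pauses) > 0) {
    pm <- do.call(rbind, pauses)
    if (any(pm[, 1] < 0) || any(pm[, 1] + pm[, 2] > duration_s) || any(pm[, 2] <= 0)) {
      abort("pauses must lie within the clip and have positive length")
    }
    pm <- pm[order(pm[, 1]), , drop = FALSE]
    if (nrow(pm) > 1 && any(pm[-1, 1] < head(pm[, 1] + pm[, 2], -1))) {
      abort("pauses must not overlap")
    }
  }
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 f0_hz = f0_hz, f0_jitter_hz = f0_jitter_hz,
                 amplitude_db = amplitude_db, n_harmonics = n_harmonics,
                 pauses = pauses),
            class = "audio_spec")
}

#' Generate a speech-surrogate audio clip with known ground truth
#'
#' A harmonic tone (fundamental plus decaying harmonics) whose F0 follows
#' a slow seeded modulation around `f0_hz`, scaled to the requested RMS
#' level and silenced over the scheduled pauses. The truth values are
#' computed analytically from the spec: the pause ratio for a given
#' minimum-pause length and the F0 target. Pure function of (spec, seed).
#'
#' @param spec An [audio_spec()].
#' @param seed Integer seed.
#' @param min_pause_s Minimum pause length used for the truth pause ratio
#'   (match the [prosody_config()] in use).
#' @return A list: `clip` ([audio_clip()]), `truth` (list with
#'   `pause_ratio`, `f0_hz`, `pause_schedule`).
#' @export
gen_audio <- function(spec = audio_spec(), seed = 1, min_pause_s = 0.3) {
  stopifnot(inherits(spec, "audio_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration_s * sr)
  rng <- local_seed(seed)

  ctrl_hop <- max(1L, round(0.01 * sr))
  n_ctrl <- ceiling(n / ctrl_hop) + 1L
  f0_ctrl <- spec$f0_hz + rng$rnorm(n_ctrl, sd = spec$f0_jitter_hz)
  f0_ctrl <- pmax(f0_ctrl, 1)
  f0_t <- stats::approx(x = (seq_len(n_ctrl) - 1L) * ctrl_hop + 1L,
                        y = f0_ctrl, xout = seq_len(n))$y
  phase <- 2 * pi * cumsum(f0_t) / sr
  x <- rep(0, n)
  for (h in seq_len(spec$n_harmonics)) {
    x <- x + 0.6^(h - 1) * sin(h * phase)
  }
  x <- x / sqrt(mean(x^2)) * 10^(spec$amplitude_db / 20)
  x <- pmin(pmax(x, -1), 1)

  for (p in spec$pauses) {
    i0 <- floor(p[1] * sr) + 1L
    i1 <- min(n, floor((p[1] + p[2]) * sr))
    x[i0:i1] <- 0
  }
  lens <- vapply(spec$pauses, `[`, numeric(1), 2)
  truth_ratio <- if (length(lens)) sum(lens[lens >= min_pause_s]) / spec$duration_s else 0
  list(clip = audio_clip(x, sr),
       truth = list(pause_ratio = truth_ratio, f0_hz = spec$f0_hz,
                    pause_schedule = spec$pauses))
}

#' Generate a model cohort and linearly rated narratives
#'
#' `gen_cohort()` draws per-speaker narrative features from independent
#' normal distributions with the given means and sds (count features
#' rounded to non-negative integers, ratio features clamped to \[0, 1\]).
#' `gen_ratings()` produces skill ratings on the 0-100 scale as a declared
#' linear combination of the score features plus Gaussian noise, returning
#' the generating weights as ground truth. Both are pure functions of
#' their arguments and the seed.
#'
#' @param n_models Number of model speakers (>= 2).
#' @param means,sds Named numeric vectors over the feature set; defaults
#'   are plausible one-minute-narrative values for the full ten-feature
#'   set.
#' @param seed Integer seed.
#' @return `gen_cohort()`: a tibble with one row per model speaker.
#' @export
gen_cohort <- function(n_models = 20,
                       means = c(smiling_ratio = 0.35, yaw_abs_mean = 8,
                                 pitch_mean = 5, f0_variation = 2,
                                 amplitude = -22, voice_quality = 0.01,
                                 pause_ratio = 0.2, words_per_minute = 120,
                                 long_word_count = 8, filler_count = 5),
                       sds = c(smiling_ratio = 0.1, yaw_abs_mean = 3,
                               pitch_mean = 4, f0_variation = 0.5,
                               amplitude = 3, voice_quality = 0.003,
                               pause_ratio = 0.05, words_per_minute = 20,
                               long_word_count = 3, filler_count = 2),
                       seed = 1) {
  if (n_models < 2) abort("cohort needs at least 2 model speakers")
  if (!identical(names(means), names(sds))) abort("means and sds must share names")
  if (any(sds <= 0)) abort("feature sds must be positive")
  rng <- local_seed(seed)
  out <- purrr::map(names(means), function(f) {
    v <- rng$rnorm(n_models, means[[f]], sds[[f]])
    if (f %in% c("smiling_ratio", "pause_ratio")) v <- pmin(pmax(v, 0), 1)
    if (f %in% c("long_word_count", "filler_count")) v <- pmax(round(v), 0)
    if (f %in% c("yaw_abs_mean", "f0_variation", "voice_quality")) v <- pmax(v, 0)
    v
  })
  names(out) <- names(means)
  tibble::as_tibble(out)
}

#' @rdname gen_cohort
#' @param cohort A feature data frame (one row per rated narrative).
#' @param weights Named generating weights over [score_feature_names()].
#' @param intercept Generating intercept on the 0-100 scale.
#' @param noise_sd Rating noise sd (0-100 scale); 0 gives exactly linear
#'   ratings.
#' @return `gen_ratings()`: a list with `ratings` (numeric, 0-100 scale),
#'   `truth_weights`, `truth_intercept`, `noise_sd`.
#' @export
gen_ratings <- function(cohort,
                        weights = c(words_per_minute = 0.2, amplitude = 0.8,
                                    long_word_count = 1.0, smiling_ratio = 40),
                        intercept = 40, noise_sd = 5, seed = 1) {
  missing <- setdiff(names(weights), names(cohort))
  if (length(missing)) {
    abort(paste0("cohort is missing feature(s): ", paste(missing, collapse = ", ")))
  }
  rng <- local_seed(seed)
  x <- as.matrix(cohort[, names(weights), drop = FALSE])
  ratings <- intercept + drop(x %*% weights) + rng$rnorm(nrow(x), sd = noise_sd)
  list(ratings = ratings, truth_weights = weights,
       truth_intercept = intercept, noise_sd = noise_sd)
}

# seeded RNG sandbox: draws do not disturb the caller's RNG state
local_seed <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      fn(...)
    }
  }
  list(rnorm = with_state(stats::rnorm), runif = with_state(stats::runif))
}
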