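test_that("face features follow hand-computed geometry", {
  tpl <- landmark_templates()$neutral
  pts <- tpl
  # lip corners at (30,50) and (60,50); collapse both eyes to centroids 40 px apart
  pts[49, ] <- c(30, 50)  # landmark 48
  pts[55, ] <- c(60, 50)  # landmark 54
  pts[37:42, ] <- matrix(rep(c(80, 82), each = 6), 6)
  pts[43:48, ] <- matrix(rep(c(120, 82), each = 6), 6)
  ff <- face_features(frame_from_points(pts))
  expect_equal(ff$lip_corner_distance, 30 / 40)
  expect_equal(ff$eye_opening, 0)

  # upper lids at y=10, lower lids at y=14, inter-ocular 40 -> opening 0.1
  pts2 <- tpl
  pts2[37:42, ] <- cbind(c(70, 76, 84, 90, 84, 76), c(12, 10, 10, 12, 14, 14))
  pts2[43:48, ] <- cbind(c(110, 116, 124, 130, 124, 116), c(12, 10, 10, 12, 14, 14))
  ff2 <- face_features(frame_from_points(pts2))
  expect_equal(ff2$eye_opening, 4 / 40)
})

test_that("face features are invariant to translation and uniform scaling", {
  tpl <- landmark_templates()$happy
  base <- face_features(frame_from_points(tpl))
  scaled <- face_features(frame_from_points(tpl * 2))
  shifted <- face_features(frame_from_points(tpl + 17.3))
  feats <- face_feature_names()
  expect_equal(as.numeric(scaled[1, feats]), as.numeric(base[1, feats]))
  expect_equal(as.numeric(shifted[1, feats]), as.numeric(base[1, feats]))
})

test_that("degenerate and missing-landmark frames are handled", {
  tpl <- landmark_templates()$neutral
  collapsed <- tpl
  collapsed[37:48, 1] <- 100  # both eye centroids at the same x
  collapsed[37:48, 2] <- 82
  expect_error(face_features(frame_from_points(collapsed)), "inter-ocular")

  track <- template_track(tpl, n_frames = 3)
  track$x48[2] <- NA
  ff <- face_features(track)
  expect_true(is.na(ff$lip_corner_distance[2]))
  expect_false(anyNA(ff$lip_corner_distance[c(1, 3)]))
})

test_that("smile training separates synthetic clusters and is consistent", {
  train <- gen_smile_training_features(shift = 3, seed = 11)
  happy <- train[train$label == "happy", ]
  neutral <- train[train$label == "neutral", ]
  m <- fixture_smile_model()

  # separable case: training accuracy 1 at 3-sd separation
  labels <- classify_frames(train, m)
  expect_equal(as.character(labels),
               ifelse(train$label == "happy", "smiling", "neutral"))

  # centroid classification
  feats <- face_feature_names()
  hc <- as.data.frame(t(colMeans(happy[, feats])))
  nc <- as.data.frame(t(colMeans(neutral[, feats])))
  expect_equal(as.character(classify_frames(hc, m)), "smiling")
  expect_equal(as.character(classify_frames(nc, m)), "neutral")
})

test_that("classifier agrees with brute-force decision evaluation", {
  m <- fixture_smile_model()
  set.seed(42)
  feats <- face_feature_names()
  random <- as.data.frame(matrix(abs(rnorm(100 * 6, mean = 0.4, sd = 0.3)), 100, 6))
  names(random) <- feats
  dec <- smile_decision_values(random, m)
  oracle <- vapply(seq_len(100), function(i) oracle_decision(m, random[i, ]),
                   numeric(1))
  expect_equal(dec, oracle, tolerance = 1e-12)
  expect_equal(as.character(classify_frames(random, m)),
               ifelse(oracle > 0, "smiling", "neutral"))
})

test_that("a frame exactly on the decision boundary is labelled neutral", {
  feats <- face_feature_names()
  # hand-built model with exact arithmetic: w = (1, -1, 0, 0, 0, 0), b = 0
  m <- structure(list(
    weights = stats::setNames(c(1, -1, 0, 0, 0, 0), feats),
    bias = 0,
    feature_means = stats::setNames(rep(0, 6), feats),
    feature_sds = stats::setNames(rep(1, 6), feats),
    regularization = 1, dropped = character()
  ), class = "smile_model")
  row <- as.data.frame(t(stats::setNames(rep(0.25, 6), feats)))
  expect_identical(smile_decision_values(row, m), 0)
  expect_equal(as.character(classify_frames(row, m)), "neutral")
  above <- row; above[[feats[1]]] <- 0.3
  expect_equal(as.character(classify_frames(above, m)), "smiling")
})

test_that("degenerate training inputs error", {
  train <- gen_smile_training_features(seed = 11)
  neutral <- train[train$label == "neutral", ]
  expect_error(train_smile_model(neutral, neutral), "identical")
  happy <- train[train$label == "happy", ]
  h2 <- happy; h2$eye_opening <- 0.2
  n2 <- neutral; n2$eye_opening <- 0.2
  expect_error(train_smile_model(h2, n2, on_constant = "error"), "constant")
  expect_warning(m <- train_smile_model(h2, n2, on_constant = "drop"), "dropping")
  expect_equal(unname(m$weights["eye_opening"]), 0)
  expect_length(m$weights, 6)
})

test_that("smiling ratio is an exact per-frame count without smoothing", {
  m <- fixture_smile_model()
  tpl <- landmark_templates()
  happy_track <- template_track(tpl$happy, n_frames = 30)
  neutral_track <- template_track(tpl$neutral, n_frames = 90)
  neutral_track$frame <- neutral_track$frame + 30L
  neutral_track$t <- neutral_track$t + 3
  mixed <- as_landmark_track(rbind(happy_track, neutral_track))
  expect_equal(smiling_ratio(mixed, m)$smiling_ratio, 30 / 120)
  expect_equal(smiling_ratio(happy_track, m)$smiling_ratio, 1)
  expect_equal(smiling_ratio(neutral_track, m)$smiling_ratio, 0)
})

test_that("frames with missing landmarks leave both numerator and denominator", {
  m <- fixture_smile_model()
  track <- template_track(landmark_templates()$happy, n_frames = 10)
  track$y48[c(3, 7)] <- NaN
  res <- smiling_ratio(track, m)
  expect_equal(res$n_dropped, 2)
  expect_equal(res$n_frames, 8)
  expect_equal(res$smiling_ratio, 1)
})

test_that("head pose summary matches hand arithmetic and the zero case", {
  tpl <- landmark_templates()$neutral
  track <- do.call(rbind, lapply(1:3, function(i) frame_from_points(tpl)))
  track$frame <- 0:2; track$t <- (0:2) / 10
  track$yaw <- c(-10, 10, 20); track$pitch <- c(-5, 15, 5)
  hp <- head_pose_summary(as_landmark_track(track))
  expect_equal(hp$yaw_abs_mean, 40 / 3)
  expect_equal(hp$pitch_mean, 5)

  zero <- template_track(tpl, n_frames = 5)
  hp0 <- head_pose_summary(zero)
  expect_equal(c(hp0$yaw_abs_mean, hp0$pitch_mean), c(0, 0))
})

test_that("mean absolute yaw dominates the absolute mean (triangle inequality)", {
  for (seed in 1:10) {
    g <- gen_landmark_track(track_spec(duration_s = 5, fps = 10,
                                       yaw_offset = seed - 5, yaw_walk_sd = 2),
                            seed = seed)
    hp <- head_pose_summary(g$track)
    expect_gte(hp$yaw_abs_mean, abs(mean(g$track$yaw)) - 1e-12)
  }
})

test_that("the YAML index-map config loads and matches the built-in default", {
  path <- system.file("extdata", "index_map.yaml", package = "sstcoach")
  imap <- read_index_map(path)
  def <- default_index_map()
  for (f in names(def)) {
    expect_equal(lapply(imap[[f]], as.integer), lapply(def[[f]], as.integer),
                 info = f)
  }
  tpl <- landmark_templates()$happy
  expect_equal(face_features(frame_from_points(tpl), imap),
               face_features(frame_from_points(tpl)))
})

test_that("landmark CSV and pose-unit handling round-trip", {
  g <- gen_landmark_track(track_spec(duration_s = 1, fps = 5), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(g$track, path)
  back <- read_landmarks(path)
  expect_equal(as.data.frame(back), as.data.frame(g$track), tolerance = 1e-12)

  rad <- g$track
  rad$yaw <- rad$yaw * pi / 180
  rad$pitch <- rad$pitch * pi / 180
  rad$roll <- rad$roll * pi / 180
  conv <- as_landmark_track(rad, pose_units = "radians")
  expect_equal(conv$yaw, g$track$yaw)

  bad <- g$track; bad$t <- rev(bad$t)
  expect_error(as_landmark_track(bad), "strictly increasing")
})
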