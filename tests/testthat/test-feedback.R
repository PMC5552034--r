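test_that("z-scores follow the cohort mean/sd definition", {
  cohort <- gen_cohort(n_models = 15, seed = 21)
  user_mean <- dplyr::summarise(cohort, dplyr::across(dplyr::everything(), mean))
  zs <- zscores(user_mean, cohort)
  expect_equal(zs$z, rep(0, nrow(zs)), tolerance = 1e-12)

  f <- "words_per_minute"
  user1 <- user_mean
  user1[[f]] <- user1[[f]] + sd(cohort[[f]])
  z1 <- zscores(user1, cohort)
  expect_equal(z1$z[z1$feature == f], 1)

  degenerate <- cohort[c(1, 1), ]
  expect_error(zscores(user_mean, degenerate), "zero")
})

test_that("z-scoring the cohort against itself standardizes every feature", {
  cohort <- gen_cohort(n_models = 25, seed = 22)
  zmat <- vapply(seq_len(nrow(cohort)),
                 function(i) zscores(cohort[i, ], cohort)$z,
                 numeric(ncol(cohort)))
  expect_equal(rowMeans(zmat), rep(0, nrow(zmat)), tolerance = 1e-10)
  expect_equal(apply(zmat, 1, sd), rep(1, nrow(zmat)), tolerance = 1e-10)
})

test_that("overall score is the clipped linear predictor", {
  user <- tibble::tibble(words_per_minute = 100, amplitude = -20,
                         long_word_count = 10, smiling_ratio = 0.4)
  zero <- list(intercept = 50,
               coef = list(words_per_minute = 0, amplitude = 0,
                           long_word_count = 0, smiling_ratio = 0))
  expect_equal(predict_overall_score(user, zero), 50)

  hot <- list(intercept = 137.2, coef = zero$coef)
  expect_equal(predict_overall_score(user, hot), 100)
  cold <- list(intercept = -4, coef = zero$coef)
  expect_equal(predict_overall_score(user, cold), 0)

  expect_error(predict_overall_score(user[, 1:3], zero), "missing feature")
})

test_that("score-model fitting recovers exact and constant generators", {
  cohort <- gen_cohort(n_models = 25, seed = 23)
  # ratings exactly linear in words per minute, other coefficients zero
  ratings <- 10 + 0.3 * cohort$words_per_minute
  m <- fit_score_model(cohort, ratings, rating_scale = c(0, 100))
  expect_equal(unname(coef(m$fit)["words_per_minute"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(coef(m$fit)[c("amplitude", "long_word_count", "smiling_ratio")]),
               rep(0, 3), tolerance = 1e-8)
  expect_equal(m$loo_r, 1, tolerance = 1e-8)

  flat <- fit_score_model(cohort, rep(4, 25), rating_scale = c(1, 7))
  expect_equal(unname(coef(flat$fit)[-1]), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(coef(flat$fit)[1]), (4 - 1) / 6 * 100, tolerance = 1e-8)
})

test_that("noisy coefficient recovery matches the normal-equations oracle", {
  cohort <- gen_cohort(n_models = 30, seed = 24)
  g <- gen_ratings(cohort, noise_sd = 5, seed = 25)
  m <- fit_score_model(cohort, g$ratings, rating_scale = c(0, 100))
  x <- cohort[, score_feature_names()]
  beta_oracle <- oracle_ols(x, g$ratings)
  expect_equal(unname(coef(m$fit)), unname(beta_oracle), tolerance = 1e-8)
  # recovered slopes within 3 standard errors of the generating weights
  se <- tidy(m)$std.error[-1]
  expect_true(all(abs(coef(m$fit)[-1] - g$truth_weights) <= 3 * se))
  # fitted values reproduce the oracle's
  fitted_oracle <- drop(cbind(1, as.matrix(x)) %*% beta_oracle)
  expect_equal(unname(predict(m$fit)), fitted_oracle, tolerance = 1e-8)
})

test_that("leave-one-out correlation from the hat matrix equals explicit refits", {
  cohort <- gen_cohort(n_models = 12, seed = 26)
  g <- gen_ratings(cohort, noise_sd = 8, seed = 27)
  m <- fit_score_model(cohort, g$ratings, rating_scale = c(0, 100))
  loo <- vapply(seq_len(12), function(i) {
    fit_i <- fit_score_model(cohort[-i, ], g$ratings[-i], rating_scale = c(0, 100))
    raw <- predict(fit_i$fit, newdata = cohort[i, score_feature_names()])
    unname(raw)
  }, numeric(1))
  expect_equal(unname(m$loo_pred), loo, tolerance = 1e-8)
  expect_equal(m$loo_r, cor(loo, g$ratings), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected", {
  cohort <- gen_cohort(n_models = 10, seed = 28)
  cohort$amplitude <- cohort$words_per_minute * 2
  expect_error(fit_score_model(cohort, rnorm(10), rating_scale = c(0, 100)),
               "rank-deficient")
})

test_that("comment selection follows the closest/median-distance rule", {
  sel3 <- select_comments(c(A = 0.1, B = 0.5, C = 2.0))
  expect_equal(sel3$positive_feature, "A")
  expect_equal(sel3$improve_feature, "B")

  z5 <- c(a = 0.2, b = 0.4, c = 0.6, d = 0.8, e = 1.0)
  expect_equal(select_comments(z5)$improve_feature, "c")   # odd: middle

  z4 <- c(p = 0.1, q = 0.3, r = 0.7, s = 0.9)
  expect_equal(select_comments(z4)$improve_feature, "q")   # even: lower middle

  expect_error(select_comments(c(only = 1)), "at least 2")
})

test_that("comment selection ignores input order and breaks ties canonically", {
  canonical <- c("A", "B", "C", "D")
  z <- c(A = -0.4, B = 0.1, C = 0.9, D = 0.4)   # |z| tie between A and D
  ref <- select_comments(z, canonical)
  set.seed(1)
  for (i in 1:10) {
    perm <- sample(names(z))
    got <- select_comments(z[perm], canonical)
    expect_identical(got, ref)
  }
  expect_equal(ref$improve_feature, "A")  # tie at 0.4 resolved by canonical order
})

test_that("the assembled report composes its parts and keeps its invariants", {
  cohort <- gen_cohort(n_models = 20, seed = 30)
  user <- dplyr::summarise(cohort, dplyr::across(dplyr::everything(), mean))
  zero_model <- list(intercept = 50,
                     coef = list(words_per_minute = 0, amplitude = 0,
                                 long_word_count = 0, smiling_ratio = 0))
  fb <- build_feedback(user, cohort, zero_model)
  expect_equal(fb$overall_score, 50)
  expect_equal(fb$radar$user_z, rep(0, 5), tolerance = 1e-12)
  # all-zero distances: canonical tie-break, improvement at the median rank (3 of 5)
  expect_equal(fb$positive_feature, feature_preset("asd5")[1])
  expect_equal(fb$improve_feature, feature_preset("asd5")[3])

  expect_equal(nrow(fb$radar), 5)          # reduced preset: exactly 5 axes
  expect_false(fb$positive_feature == fb$improve_feature)

  full <- build_feedback(cohort[3, ], cohort, zero_model,
                         features = feature_preset("full"))
  expect_equal(nrow(full$radar), 10)
  expect_false(full$positive_feature == full$improve_feature)
  expect_true(is.character(full$positive_comment) && nzchar(full$positive_comment))
})

test_that("score and feedback serialization round-trips", {
  cohort <- gen_cohort(n_models = 20, seed = 31)
  g <- gen_ratings(cohort, noise_sd = 3, seed = 32)
  m <- fit_score_model(cohort, g$ratings, rating_scale = c(0, 100),
                       standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  expect_equal(predict_overall_score(cohort, m2),
               predict_overall_score(cohort, m), tolerance = 1e-9)

  fb <- build_feedback(cohort[1, ], cohort, m2)
  pfb <- withr::local_tempfile(fileext = ".json")
  write_feedback(fb, pfb)
  obj <- jsonlite::read_json(pfb, simplifyVector = TRUE)
  expect_equal(obj$overall_score, fb$overall_score, tolerance = 1e-12)
  expect_equal(obj$positive$feature, fb$positive_feature)

  sm <- fixture_smile_model()
  psm <- withr::local_tempfile(fileext = ".json")
  write_smile_model(sm, psm)
  sm2 <- read_smile_model(psm, check_index_map = default_index_map())
  expect_equal(sm2$weights, sm$weights, tolerance = 1e-12)
  wrong_map <- default_index_map()
  wrong_map$lip_corner_distance$points <- c(49L, 55L)
  expect_error(read_smile_model(psm, check_index_map = wrong_map), "index map")
})

test_that("tidiers and the radar plot expose the report", {
  cohort <- gen_cohort(n_models = 15, seed = 33)
  g <- gen_ratings(cohort, noise_sd = 4, seed = 34)
  m <- fit_score_model(cohort, g$ratings, rating_scale = c(0, 100))
  expect_named(tidy(m), c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(m)
  expect_true(all(c("r.squared", "loo_r", "n") %in% names(gl)))

  fb <- build_feedback(cohort[2, ], cohort, m)
  td <- tidy(fb)
  expect_equal(sum(td$role == "positive", na.rm = TRUE), 1)
  expect_equal(sum(td$role == "improve", na.rm = TRUE), 1)
  p <- autoplot(fb)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_ratings(asd_ratings()), "ggplot")
})
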