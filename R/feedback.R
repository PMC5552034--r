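#' Z-scores of a user's features against the model cohort
#'
#' For every active feature, `z = (user - mean) / sd`, where mean and sd
#' (n-1 denominator) are computed over the model cohort — speakers with
#' good narrative skills whose style the user is asked to emulate. The
#' z-scores feed the radar-chart comparison and comment selection.
#'
#' @param user One-row data frame (or named list) of the user's features.
#' @param cohort Data frame, one row per model speaker, columns = features.
#' @param features Character vector of active features; defaults to the
#'   columns shared by `user` and `cohort`, in `user`'s order.
#' @return A tibble with columns `feature`, `value`, `cohort_mean`,
#'   `cohort_sd`, `z`.
#' @export
#' @examples
#' cohort <- gen_cohort(n_models = 10, seed = 1)
#' user <- dplyr::summarise(cohort, dplyr::across(dplyr::everything(), mean))
#' zscores(user, cohort)
zscores <- function(user, cohort, features = NULL) {
  user <- tibble::as_tibble(as.list(unlist(user)))
  if (is.null(features)) features <- intersect(names(user), names(cohort))
  if (length(features) == 0) abort("no shared features between user and cohort")
  missing <- setdiff(features, names(user))
  if (length(missing)) {
    abort(paste0("user is missing feature(s): ", paste(missing, collapse = ", ")))
  }
  missing_c <- setdiff(features, names(cohort))
  if (length(missing_c)) {
    abort(paste0("cohort is missing feature(s): ", paste(missing_c, collapse = ", ")))
  }
  if (nrow(cohort) < 2) abort("model cohort needs at least 2 rows")
  stats_tbl <- purrr::map_dfr(features, function(f) {
    v <- cohort[[f]]
    m <- mean(v)
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(paste0("cohort standard deviation is zero for feature `", f, "`"))
    }
    tibble::tibble(feature = f, value = as.numeric(user[[f]]),
                   cohort_mean = m, cohort_sd = s)
  })
  dplyr::mutate(stats_tbl, z = (.data$value - .data$cohort_mean) / .data$cohort_sd)
}

#' Fit the 0-100 overall-score regression model
#'
#' Fits a Gaussian identity-link linear model (ordinary least squares) of
#' trainer-rated narrative skill, rescaled to 0-100, on the four score
#' features (words per minute, amplitude, long words, smiling ratio).
#' Leave-one-out cross-validated predictions are computed in closed form
#' from the hat matrix, and their Pearson correlation with the observed
#' scores is reported as `loo_r` — the measure used to validate the score
#' display.
#'
#' @param data Data frame with the feature columns, one row per rated
#'   narrative.
#' @param ratings Numeric vector of skill ratings, one per row of `data`.
#' @param features Predictors; default [score_feature_names()].
#' @param rating_scale Two-element range of the rating instrument, mapped
#'   linearly onto 0-100. Default `c(1, 7)` (Likert 1-7); use `c(0, 100)`
#'   for ratings already on the score scale.
#' @param standardize If `TRUE`, predictors are centred/scaled before the
#'   fit (the model stores the transform, prediction is unaffected in
#'   exact arithmetic). Default `FALSE` (raw features).
#' @return An object of class `sst_score_model`.
#' @export
fit_score_model <- function(data, ratings, features = score_feature_names(),
                            rating_scale = c(1, 7), standardize = FALSE) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    abort(paste0("data is missing feature(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 2) abort("need at least 2 rated narratives")
  if (length(ratings) != nrow(data)) abort("one rating per data row required")
  if (!all(is.finite(ratings))) abort("ratings must be finite")
  y <- (ratings - rating_scale[1]) / diff(rating_scale) * 100

  x <- data[, features, drop = FALSE]
  ctr <- rep(0, length(features)); scl <- rep(1, length(features))
  if (standardize) {
    ctr <- vapply(x, mean, numeric(1))
    scl <- vapply(x, sd, numeric(1))
    if (any(scl == 0)) abort("cannot standardize a constant feature")
    x <- purrr::map2_dfc(x, seq_along(x), ~ (.x - ctr[.y]) / scl[.y])
    names(x) <- features
  }
  df <- dplyr::bind_cols(x, tibble::tibble(.score = y))
  fit <- lm(.score ~ ., data = df)
  if (anyNA(coef(fit))) abort("rank-deficient design: collinear or constant features")

  h <- stats::hatvalues(fit)
  loo_ok <- h < 1 - 1e-10
  loo_pred <- rep(NA_real_, length(y))
  loo_pred[loo_ok] <- y[loo_ok] - stats::residuals(fit)[loo_ok] / (1 - h[loo_ok])
  loo_r <- if (sum(loo_ok) >= 3 && sd(y[loo_ok]) > 0 && sd(loo_pred[loo_ok]) > 0) {
    cor(loo_pred[loo_ok], y[loo_ok])
  } else NA_real_

  structure(
    list(fit = fit, features = features, clip = c(0, 100),
         rating_scale = rating_scale, standardize = standardize,
         center = stats::setNames(ctr, features),
         scale = stats::setNames(scl, features),
         loo_r = loo_r, loo_pred = loo_pred, n = nrow(data)),
    class = "sst_score_model"
  )
}

#' @export
print.sst_score_model <- function(x, ...) {
  cat("<sst_score_model> 0-100 narrative score, OLS on",
      length(x$features), "features, n =", x$n, "\n")
  cat("  coefficients:\n")
  print(round(coef(x$fit), 4))
  cat(sprintf("  leave-one-out r = %.3f (%s features)\n",
              x$loo_r, if (x$standardize) "standardized" else "raw"))
  invisible(x)
}

#' Predict the 0-100 overall narrative score
#'
#' Linear predictor `intercept + sum(coef * feature)`, clipped to
#' \[0, 100\]. The score is the headline number shown after each role-play
#' to motivate practice.
#'
#' @param user Data frame with the model's feature columns (one or more
#'   rows).
#' @param model An `sst_score_model`, or a bare list with `intercept`,
#'   named `coef`, and optional `clip` (the serialized JSON form).
#' @return Numeric vector of scores in \[0, 100\].
#' @export
predict_overall_score <- function(user, model) {
  if (inherits(model, "sst_score_model")) {
    feats <- model$features
    missing <- setdiff(feats, names(user))
    if (length(missing)) {
      abort(paste0("user is missing feature(s): ", paste(missing, collapse = ", ")))
    }
    x <- tibble::as_tibble(user)[, feats, drop = FALSE]
    if (model$standardize) {
      x <- purrr::map2_dfc(x, seq_along(x),
                           ~ (.x - model$center[.y]) / model$scale[.y])
      names(x) <- feats
    }
    raw <- predict(model$fit, newdata = x)
    lo <- model$clip[1]; hi <- model$clip[2]
  } else {
    feats <- names(model$coef)
    missing <- setdiff(feats, names(user))
    if (length(missing)) {
      abort(paste0("user is missing feature(s): ", paste(missing, collapse = ", ")))
    }
    xm <- as.matrix(tibble::as_tibble(user)[, feats, drop = FALSE])
    raw <- drop(xm %*% unlist(model$coef)) + model$intercept
    clip <- model$clip %||% c(0, 100)
    lo <- clip[1]; hi <- clip[2]
  }
  unname(pmin(pmax(raw, lo), hi))
}

#' Write / read a score model as JSON
#'
#' Serialized form: `{"intercept": ..., "coef": {feature: value}, "clip":
#' [0, 100]}`, with the standardization transform folded into the
#' coefficients so the JSON applies to raw features.
#'
#' @param model An `sst_score_model`.
#' @param path File path.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "sst_score_model"))
  b <- coef(model$fit)
  slopes <- b[-1] / model$scale[model$features]
  intercept <- unname(b[1] - sum(slopes * model$center[model$features]))
  obj <- list(intercept = intercept,
              coef = as.list(stats::setNames(unname(slopes), model$features)),
              clip = model$clip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(intercept = obj$intercept, coef = as.list(obj$coef),
       clip = obj$clip %||% c(0, 100))
}

#' Select the positive and needs-improvement features
#'
#' The positive comment praises the feature whose value is *closest* to the
#' models (smallest |z|). The improvement comment targets the feature at
#' the *median* distance from the models, not the farthest: asking users
#' with social-communication difficulties to fix their single worst point
#' is often counter-productive, so the mid-ranked deviation is coached
#' instead. With distances sorted ascending, the improvement feature sits
#' at rank `floor((n + 1) / 2)` (odd n: the middle; even n: the lower
#' middle), never below rank 2 so it differs from the praised feature.
#' Ties in |z| are broken by canonical feature order, so the selection does
#' not depend on input ordering.
#'
#' @param z Either the tibble returned by [zscores()] or a named numeric
#'   vector of z-scores.
#' @param canonical_order Tie-break order; defaults to the order of the
#'   active features as given.
#' @return A list with `positive_feature` and `improve_feature`.
#' @export
#' @examples
#' select_comments(c(A = 0.1, B = -0.5, C = 2.0))
select_comments <- function(z, canonical_order = NULL) {
  if (is.data.frame(z)) z <- stats::setNames(z$z, z$feature)
  if (is.null(names(z)) || any(!nzchar(names(z)))) abort("z-scores must be named")
  if (length(z) < 2) abort("comment selection needs at least 2 features")
  if (any(!is.finite(z))) abort("z-scores must be finite")
  if (is.null(canonical_order)) canonical_order <- names(z)
  d <- abs(z)
  ord <- order(d, match(names(z), canonical_order))
  n <- length(z)
  improve_rank <- max(2L, floor((n + 1) / 2))
  list(positive_feature = names(z)[ord[1]],
       improve_feature = names(z)[ord[improve_rank]])
}

#' Default feedback comment templates
#'
#' Template text per feature and direction of deviation (sign of z), in a
#' named-list pack: `templates[[feature]]$positive`, `$improve_low` (user
#' below the models), `$improve_high`. The shipped packs are English
#' (`"en"`) and Japanese (`"ja"`, romanized); any list with the same shape
#' can be substituted.
#'
#' @param lang `"en"` or `"ja"`.
#' @return Named list of per-feature template triples.
#' @export
default_comment_templates <- function(lang = c("en", "ja")) {
  lang <- match.arg(lang)
  mk <- function(pos, lo, hi) list(positive = pos, improve_low = lo, improve_high = hi)
  if (lang == "en") {
    list(
      smiling_ratio = mk("Your smiling was just like the model speakers. Keep it up!",
                         "Try smiling a little more while you talk.",
                         "Try relaxing your smile a little so it feels natural."),
      yaw_abs_mean = mk("You faced the listener just like the models.",
                        "You are doing well facing forward; keep it steady.",
                        "Try to face the listener a little more directly."),
      pitch_mean = mk("Your head position was just like the models.",
                      "Try lifting your head a little while you speak.",
                      "Try not to look down so much while you speak."),
      f0_variation = mk("Your intonation was lively, like the models.",
                        "Try varying your tone a little more.",
                        "Try keeping your tone a little steadier."),
      amplitude = mk("Your voice volume matched the models well.",
                     "Try speaking a little louder.",
                     "Try speaking a little more softly."),
      voice_quality = mk("Your voice sounded clear and steady.",
                         "Try to keep your voice steady.",
                         "Try to keep your voice steady."),
      pause_ratio = mk("Your pacing of pauses matched the models.",
                       "A few more pauses would give listeners time to follow.",
                       "Try to pause a little less often."),
      words_per_minute = mk("Your speaking speed matched the models well.",
                            "Try speaking a little faster.",
                            "Try speaking a little more slowly."),
      long_word_count = mk("Your vocabulary was rich, like the models.",
                           "Try using a few more descriptive words.",
                           "Try using simpler words so everyone follows."),
      filler_count = mk("You used few fillers, just like the models.",
                        "You used few fillers; well done.",
                        "Try to reduce fillers like 'eto' and 'anou'.")
    )
  } else {
    list(
      smiling_ratio = mk("Egao ga moderu to onaji kurai deshita. Sono choushi!",
                         "Mou sukoshi egao de hanashite mimashou.",
                         "Egao o sukoshi shizen ni shite mimashou."),
      yaw_abs_mean = mk("Kichinto aite no hou o muite hanasemashita.",
                        "Shoumen o muite hanasu no o tsuzukemashou.",
                        "Mou sukoshi aite no hou o muite hanashimashou."),
      pitch_mean = mk("Atama no muki ga moderu to onaji deshita.",
                      "Sukoshi kao o agete hanashite mimashou.",
                      "Shita o muki suginai you ni shimashou."),
      f0_variation = mk("Yokuyou ga yutaka deshita.",
                        "Mou sukoshi yokuyou o tsukete mimashou.",
                        "Yokuyou o sukoshi osaete mimashou."),
      amplitude = mk("Koe no ookisa ga choudo yokatta desu.",
                     "Mou sukoshi ookina koe de hanashimashou.",
                     "Mou sukoshi shizuka ni hanashimashou."),
      voice_quality = mk("Koe ga antei shite imashita.",
                         "Koe o antei sasete mimashou.",
                         "Koe o antei sasete mimashou."),
      pause_ratio = mk("Ma no torikata ga jouzu deshita.",
                       "Mou sukoshi ma o totte mimashou.",
                       "Ma o sukoshi herashite mimashou."),
      words_per_minute = mk("Hanasu hayasa ga choudo yokatta desu.",
                            "Mou sukoshi hayaku hanashite mimashou.",
                            "Mou sukoshi yukkuri hanashimashou."),
      long_word_count = mk("Iroirona kotoba o tsukaemashita.",
                           "Mou sukoshi kuwashii kotoba o tsukatte mimashou.",
                           "Mou sukoshi kantan na kotoba o tsukaimashou."),
      filler_count = mk("'Eto' nado ga sukunakute yokatta desu.",
                        "'Eto' nado ga sukunakute yokatta desu.",
                        "'Eto' ya 'anou' o herashite mimashou.")
    )
  }
}

#' Assemble the feedback report for one role-play
#'
#' Combines z-scoring, score prediction and comment selection into the
#' feedback shown after a role-play: the overall 0-100 score, the
#' radar-chart comparison (user z-scores against the cohort baseline at 0),
#' and one positive plus one needs-improvement comment.
#'
#' @param user One-row data frame of the user's narrative features.
#' @param cohort Model-cohort feature data frame.
#' @param score_model An `sst_score_model` or serialized score-model list.
#' @param templates Comment templates, see [default_comment_templates()].
#' @param features Active feature set (canonical order); default the
#'   `"asd5"` preset.
#' @return An object of class `sst_feedback` with fields `overall_score`,
#'   `zscores` (tibble), `positive_feature`, `positive_comment`,
#'   `improve_feature`, `improve_comment`, `radar` (tibble of feature,
#'   user_z, model_z).
#' @export
build_feedback <- function(user, cohort, score_model,
                           templates = default_comment_templates(),
                           features = feature_preset("asd5")) {
  zs <- zscores(user, cohort, features)
  score <- predict_overall_score(user, score_model)
  sel <- select_comments(stats::setNames(zs$z, zs$feature),
                         canonical_order = features)
  comment_for <- function(feature, role) {
    tpl <- templates[[feature]]
    if (is.null(tpl)) return(sprintf("(%s: no template)", feature))
    if (role == "positive") return(tpl$positive)
    z <- zs$z[zs$feature == feature]
    if (z < 0) tpl$improve_low else tpl$improve_high
  }
  structure(
    list(
      overall_score = score,
      zscores = zs,
      positive_feature = sel$positive_feature,
      positive_comment = comment_for(sel$positive_feature, "positive"),
      improve_feature = sel$improve_feature,
      improve_comment = comment_for(sel$improve_feature, "improve"),
      radar = tibble::tibble(feature = factor(zs$feature, levels = features),
                             user_z = zs$z, model_z = 0)
    ),
    class = "sst_feedback"
  )
}

#' @export
print.sst_feedback <- function(x, ...) {
  cat(sprintf("<sst_feedback> overall score %.1f / 100\n", x$overall_score))
  cat("  z-scores: ",
      paste(sprintf("%s=%+.2f", x$zscores$feature, x$zscores$z), collapse = ", "),
      "\n", sep = "")
  cat("  + ", x$positive_feature, ": ", x$positive_comment, "\n", sep = "")
  cat("  ~ ", x$improve_feature, ": ", x$improve_comment, "\n", sep = "")
  invisible(x)
}

#' Serialize a feedback report to JSON
#'
#' @param report An `sst_feedback`.
#' @param path File path.
#' @export
write_feedback <- function(report, path) {
  stopifnot(inherits(report, "sst_feedback"))
  obj <- list(
    overall_score = report$overall_score,
    zscores = stats::setNames(as.list(report$zscores$z), report$zscores$feature),
    positive = list(feature = report$positive_feature,
                    comment = report$positive_comment),
    improve = list(feature = report$improve_feature,
                   comment = report$improve_comment),
    radar = list(features = as.character(report$radar$feature),
                 user_z = report$radar$user_z,
                 model_z = report$radar$model_z)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
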