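#' Train the linear smile/neutral classifier
#'
#' Fits a linear-kernel support vector machine separating happy from neutral
#' faces in the six-dimensional geometric feature space. Features are
#' standardized with the pooled training mean and standard deviation before
#' fitting; the returned model carries the standardization parameters so the
#' same transform is applied at prediction time. The decision function is
#' oriented so that positive values mean smiling.
#'
#' @param happy,neutral Data frames of face features (columns of
#'   [face_feature_names()]), one row per training face.
#' @param regularization SVM cost parameter C (default 1).
#' @param on_constant What to do with a feature that is constant across all
#'   training rows: `"error"` (default) or `"drop"` (weight fixed at zero,
#'   with a warning).
#' @return An object of class `smile_model`: named `weights` (length 6),
#'   `bias`, `feature_means`, `feature_sds`, plus the cost and any dropped
#'   features.
#' @export
#' @examples
#' set.seed(1)
#' train <- gen_smile_training_features(seed = 1)
#' m <- train_smile_model(train[train$label == "happy", ],
#'                        train[train$label == "neutral", ])
#' m$weights
train_smile_model <- function(happy, neutral, regularization = 1,
                              on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  feats <- face_feature_names()
  happy <- as.data.frame(happy)[, feats, drop = FALSE]
  neutral <- as.data.frame(neutral)[, feats, drop = FALSE]
  if (nrow(happy) == 0 || nrow(neutral) == 0) {
    abort("both the happy and the neutral training sets must be non-empty")
  }
  x <- rbind(as.matrix(happy), as.matrix(neutral))
  if (!all(is.finite(x))) abort("training features must all be finite")
  y <- factor(c(rep("smiling", nrow(happy)), rep("neutral", nrow(neutral))),
              levels = c("neutral", "smiling"))

  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    if (on_constant == "error") {
      abort(paste0("feature(s) constant across the training set: ",
                   paste(feats[constant], collapse = ", ")))
    }
    warn(paste0("dropping constant training feature(s): ",
                paste(feats[constant], collapse = ", ")))
    sds[constant] <- 1
  }
  xs <- sweep(sweep(x, 2, mu), 2, sds, "/")
  active <- !constant
  if (!any(active)) abort("no non-constant features left to train on")
  sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  if (nrow(happy) == nrow(neutral) &&
      isTRUE(all.equal(sort_rows(as.matrix(happy)), sort_rows(as.matrix(neutral)),
                       check.attributes = FALSE))) {
    abort("degenerate training data: happy and neutral classes are identical")
  }

  fit <- e1071::svm(x = xs[, active, drop = FALSE], y = y, kernel = "linear",
                    cost = regularization, scale = FALSE)
  w_active <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  weights <- stats::setNames(numeric(length(feats)), feats)
  weights[active] <- w_active
  # orient so that the happy training centroid has a positive decision value
  dec_happy <- mean(xs[y == "smiling", , drop = FALSE] %*% weights + b)
  if (dec_happy < 0) {
    weights <- -weights
    b <- -b
  }
  structure(
    list(weights = weights, bias = b,
         feature_means = stats::setNames(mu, feats),
         feature_sds = stats::setNames(sds, feats),
         regularization = regularization,
         dropped = feats[constant]),
    class = "smile_model"
  )
}

#' @export
print.smile_model <- function(x, ...) {
  cat("<smile_model> linear SVM over", length(x$weights), "face features\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat("  bias:", format(x$bias, digits = 4), "\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Decision values and smile labels for face-feature rows
#'
#' `smile_decision_values()` returns the signed distance-like decision value
#' `w . standardize(x) + b` for each row; `classify_frames()` thresholds it:
#' a frame is *smiling* iff the decision value is strictly positive (an
#' exact zero is labelled neutral — smiling requires positive evidence).
#'
#' @param features A data frame containing the six face-feature columns.
#'   Rows with any non-finite feature raise an error.
#' @param model A `smile_model`.
#' @return `smile_decision_values()`: numeric vector. `classify_frames()`:
#'   factor with levels `neutral`, `smiling`.
#' @export
smile_decision_values <- function(features, model) {
  stopifnot(inherits(model, "smile_model"))
  feats <- names(model$weights)
  x <- as.matrix(as.data.frame(features)[, feats, drop = FALSE])
  if (!all(is.finite(x))) abort("non-finite face features; drop NA frames first")
  xs <- sweep(sweep(x, 2, model$feature_means), 2, model$feature_sds, "/")
  drop(xs %*% model$weights + model$bias)
}

#' @rdname smile_decision_values
#' @export
classify_frames <- function(features, model) {
  dec <- smile_decision_values(features, model)
  factor(ifelse(dec > 0, "smiling", "neutral"), levels = c("neutral", "smiling"))
}

#' Smiling ratio of a landmark track
#'
#' Classifies every frame of the track as smiling or neutral with the linear
#' smile model and returns the proportion of smiling frames. There is no
#' temporal smoothing: the ratio is a pure per-frame count. Frames with
#' missing landmarks are excluded from both numerator and denominator; the
#' number excluded is returned as `n_dropped`.
#'
#' @param track A landmark-track tibble.
#' @param model A `smile_model`.
#' @param index_map See [default_index_map()].
#' @return A one-row tibble: `smiling_ratio` in \[0, 1\], `n_smiling`,
#'   `n_frames` (frames used), `n_dropped`.
#' @export
smiling_ratio <- function(track, model, index_map = default_index_map()) {
  if (nrow(track) == 0) abort("landmark track must contain at least one frame")
  ff <- face_features(track, index_map)
  ok <- stats::complete.cases(ff[, face_feature_names()])
  if (!any(ok)) abort("no frames with complete landmarks")
  labels <- classify_frames(ff[ok, ], model)
  tibble::tibble(
    smiling_ratio = mean(labels == "smiling"),
    n_smiling = sum(labels == "smiling"),
    n_frames = sum(ok),
    n_dropped = sum(!ok)
  )
}

#' Serialize / restore a smile model as JSON
#'
#' The JSON carries the weights, bias, standardization statistics, cost and
#' a hash of the index map the features were extracted with, so a model is
#' never silently applied to features from a different geometry.
#'
#' @param model A `smile_model`.
#' @param path File path for the JSON.
#' @param index_map The index map the model's features came from (hashed).
#' @export
write_smile_model <- function(model, path, index_map = default_index_map()) {
  stopifnot(inherits(model, "smile_model"))
  obj <- list(
    weights = as.list(model$weights), bias = model$bias,
    feature_means = as.list(model$feature_means),
    feature_sds = as.list(model$feature_sds),
    regularization = model$regularization,
    dropped = model$dropped,
    index_map_hash = rlang::hash(index_map)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_smile_model
#' @param check_index_map If not `NULL`, an index map whose hash must match
#'   the one stored with the model.
#' @export
read_smile_model <- function(path, check_index_map = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(check_index_map) &&
      !identical(obj$index_map_hash, rlang::hash(check_index_map))) {
    abort("smile model was trained under a different landmark index map")
  }
  structure(
    list(weights = unlist(obj$weights), bias = obj$bias,
         feature_means = unlist(obj$feature_means),
         feature_sds = unlist(obj$feature_sds),
         regularization = obj$regularization,
         dropped = as.character(obj$dropped %||% character())),
    class = "smile_model"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
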