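#' Landmark tracks
#'
#' A landmark track is a tibble with one row per video frame and columns
#' `frame`, `t` (seconds from track start), `x0..x65`, `y0..y65` (pixel
#' coordinates of the 66 landmark points) and `yaw`, `pitch`, `roll` (head
#' pose in degrees; yaw positive = head turned to the subject's left, pitch
#' positive = facing down, roll carried but unused). `t` must be strictly
#' increasing and non-negative.
#'
#' @param data A data frame with the columns above.
#' @param pose_units `"degrees"` (default) or `"radians"`; radians are
#'   converted to degrees on the way in.
#' @return A validated landmark-track tibble.
#' @export
as_landmark_track <- function(data, pose_units = c("degrees", "radians")) {
  pose_units <- match.arg(pose_units)
  data <- tibble::as_tibble(data)
  needed <- landmark_columns()
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("landmark track is missing columns: ",
                 paste(head(missing, 6), collapse = ", "),
                 if (length(missing) > 6) ", ..." else ""))
  }
  if (nrow(data) == 0) abort("landmark track must contain at least one frame")
  if (any(!is.finite(data$t)) || any(data$t < 0)) {
    abort("frame times `t` must be finite and >= 0")
  }
  if (nrow(data) > 1 && any(diff(data$t) <= 0)) {
    abort("frame times `t` must be strictly increasing")
  }
  if (pose_units == "radians") {
    for (col in c("yaw", "pitch", "roll")) data[[col]] <- data[[col]] * 180 / pi
  }
  data
}

landmark_columns <- function() {
  c("frame", "t", paste0("x", 0:65), paste0("y", 0:65), "yaw", "pitch", "roll")
}

#' Read / write a landmark track CSV
#'
#' The CSV has header `frame,t,x0..x65,y0..y65,yaw,pitch,roll`, one row per
#' frame, UTF-8, decimal point.
#'
#' @param path File path.
#' @param pose_units Units of the pose columns in the file; see
#'   [as_landmark_track()].
#' @return `read_landmarks()` returns a validated landmark-track tibble.
#' @export
read_landmarks <- function(path, pose_units = c("degrees", "radians")) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_landmark_track(data, pose_units = match.arg(pose_units))
}

#' @rdname read_landmarks
#' @param track A landmark-track tibble.
#' @export
write_landmarks <- function(track, path) {
  readr::write_csv(track[, landmark_columns()], path, progress = FALSE)
  invisible(path)
}

#' Extract geometric face features from a landmark track
#'
#' Converts each frame's 66 landmark points into the six geometric face
#' features used by the smile classifier: outer and inner eyebrow height,
#' outer and inner lip height, eye opening, and lip corner distance. Heights
#' are mean vertical distances between the upper and lower point sets named
#' in `index_map`; the lip corner distance is Euclidean. Every value is
#' divided by the inter-ocular distance (distance between the two
#' eye-centroid points), making the features dimensionless and invariant to
#' translation and uniform scaling.
#'
#' Frames containing non-finite coordinates among the used landmarks yield
#' `NA` features; downstream summaries exclude such frames (with a count)
#' rather than failing, since tracker dropouts are routine.
#'
#' @param track A landmark-track tibble (see [as_landmark_track()]); a bare
#'   data frame with the landmark columns is accepted.
#' @param index_map Feature-to-landmark mapping, see [default_index_map()].
#' @return A tibble with columns `frame`, `t` and the six features, one row
#'   per input frame.
#' @export
#' @examples
#' tpl <- landmark_templates()
#' track <- template_track(tpl$neutral, n_frames = 2)
#' face_features(track)
face_features <- function(track, index_map = default_index_map()) {
  index_map <- validate_index_map(index_map)
  if (nrow(track) == 0) abort("landmark track must contain at least one frame")
  xs <- unname(as.matrix(track[, paste0("x", 0:65)]))
  ys <- unname(as.matrix(track[, paste0("y", 0:65)]))
  col1 <- function(idx) idx + 1L  # 0-based index -> matrix column

  set_mean <- function(m, idx) {
    if (length(idx) == 1L) m[, col1(idx)] else rowMeans(m[, col1(idx), drop = FALSE])
  }

  lx <- set_mean(xs, index_map$eye_centers$left)
  ly <- set_mean(ys, index_map$eye_centers$left)
  rx <- set_mean(xs, index_map$eye_centers$right)
  ry <- set_mean(ys, index_map$eye_centers$right)
  iod <- sqrt((lx - rx)^2 + (ly - ry)^2)
  if (any(is.finite(iod) & iod == 0)) {
    abort("degenerate face: inter-ocular distance is zero in at least one frame")
  }

  height <- function(spec) {
    abs(set_mean(ys, spec$lower) - set_mean(ys, spec$upper)) / iod
  }
  p <- index_map$lip_corner_distance$points
  lip_corner <- sqrt((xs[, col1(p[1])] - xs[, col1(p[2])])^2 +
                     (ys[, col1(p[1])] - ys[, col1(p[2])])^2) / iod

  out <- tibble::tibble(
    frame = track$frame,
    t = track$t,
    outer_eyebrow_height = height(index_map$outer_eyebrow_height),
    inner_eyebrow_height = height(index_map$inner_eyebrow_height),
    outer_lip_height     = height(index_map$outer_lip_height),
    inner_lip_height     = height(index_map$inner_lip_height),
    eye_opening          = height(index_map$eye_opening),
    lip_corner_distance  = lip_corner
  )
  # a frame with any non-finite used coordinate propagates to NA features
  bad <- !is.finite(iod)
  if (any(bad)) out[bad, face_feature_names()] <- NA_real_
  out
}

#' Summarize head pose over a track
#'
#' Mean absolute yaw (shift from frontal, degrees) and signed mean pitch
#' (degrees; positive = facing down, negative = facing up), averaged over
#' all frames with finite pose values. Frames with missing pose are excluded
#' from both numerator and denominator and counted in `n_dropped`.
#'
#' @param track A landmark-track tibble.
#' @return A one-row tibble with `yaw_abs_mean`, `pitch_mean`, `n_frames`,
#'   `n_dropped`.
#' @export
head_pose_summary <- function(track) {
  if (nrow(track) == 0) abort("landmark track must contain at least one frame")
  ok <- is.finite(track$yaw) & is.finite(track$pitch)
  if (!any(ok)) abort("no frames with finite head-pose values")
  tibble::tibble(
    yaw_abs_mean = mean(abs(track$yaw[ok])),
    pitch_mean   = mean(track$pitch[ok]),
    n_frames     = sum(ok),
    n_dropped    = sum(!ok)
  )
}
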