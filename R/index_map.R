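#' Default landmark index map for the 66-point annotation
#'
#' The geometric face features are defined over a 66-point facial-landmark
#' annotation (17 jaw, 10 brow, 9 nose, 12 eye, 18 mouth points, 0-based
#' indices as in the landmark CSV header `x0..x65`):
#'
#' * jaw outline: 0-16
#' * brows: 17-21 (image-left), 22-26 (image-right)
#' * nose: 27-35
#' * eyes: 36-41 (image-left), 42-47 (image-right)
#' * mouth: 48-59 (outer lip), 60-65 (inner lip)
#'
#' Each *height* feature is the mean vertical (y) distance between an upper
#' and a lower point set; `lip_corner_distance` is the Euclidean distance
#' between the two mouth corners. All distances are divided by the
#' inter-ocular distance (distance between the two eye-centroid points), so
#' features are invariant to translation and uniform scale. The mapping is a
#' documented, overridable configuration, not ground truth of any particular
#' tracker: pass a modified list, or a YAML file via [read_index_map()], to
#' every extraction function that takes `index_map`.
#'
#' @return A named list with one entry per feature. Height features hold
#'   `upper` and `lower` integer vectors of 0-based landmark indices;
#'   `lip_corner_distance` holds `points` (exactly two indices);
#'   `eye_centers` holds `left` and `right` index sets whose centroids
#'   define the inter-ocular distance.
#' @seealso [face_features()], [read_index_map()]
#' @export
#' @examples
#' default_index_map()$eye_opening
default_index_map <- function() {
  list(
    outer_eyebrow_height = list(upper = c(17L, 26L), lower = c(36L, 45L)),
    inner_eyebrow_height = list(upper = c(21L, 22L), lower = c(39L, 42L)),
    outer_lip_height     = list(upper = c(50L, 51L, 52L), lower = c(56L, 57L, 58L)),
    inner_lip_height     = list(upper = c(60L, 61L, 62L), lower = c(63L, 64L, 65L)),
    eye_opening          = list(upper = c(37L, 38L, 43L, 44L), lower = c(40L, 41L, 46L, 47L)),
    lip_corner_distance  = list(points = c(48L, 54L)),
    eye_centers          = list(left = 36:41, right = 42:47)
  )
}

#' Names of the six geometric face features
#' @return Character vector in canonical order.
#' @export
face_feature_names <- function() {
  c("outer_eyebrow_height", "inner_eyebrow_height",
    "outer_lip_height", "inner_lip_height",
    "eye_opening", "lip_corner_distance")
}

#' Read a landmark index map from a YAML config
#'
#' Reads the `visual:` section (or the whole document if no such section) of
#' a YAML file laid out like [default_index_map()].
#'
#' @param path Path to a YAML file.
#' @return Index-map list, validated.
#' @export
read_index_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$visual)) cfg <- cfg$visual
  if (!is.null(cfg$index_map)) cfg <- cfg$index_map
  validate_index_map(cfg)
}

validate_index_map <- function(index_map) {
  needed <- c(face_feature_names(), "eye_centers")
  missing <- setdiff(needed, names(index_map))
  if (length(missing) > 0) {
    abort(paste0("index_map is missing entries: ", paste(missing, collapse = ", ")))
  }
  all_idx <- unlist(index_map[needed], use.names = FALSE)
  all_idx <- as.integer(all_idx)
  if (anyNA(all_idx) || any(all_idx < 0L) || any(all_idx > 65L)) {
    abort("index_map landmark indices must be integers in 0..65")
  }
  if (length(index_map$lip_corner_distance$points) != 2L) {
    abort("lip_corner_distance must name exactly two landmark points")
  }
  index_map
}
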