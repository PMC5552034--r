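#' Tidy a fitted score model
#'
#' Broom-style coefficient table for the 0-100 score regression.
#'
#' @param x An `sst_score_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.sst_score_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.sst_score_model
#' @return `glance()`: one-row tibble with `r.squared`, `sigma`, `loo_r`
#'   (leave-one-out predicted-vs-observed Pearson correlation), `n`,
#'   `standardized`.
#' @export
glance.sst_score_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    loo_r = x$loo_r,
    n = x$n,
    standardized = x$standardize
  )
}

#' Tidy a feedback report
#'
#' @param x An `sst_feedback`.
#' @param ... Unused.
#' @return The z-score tibble with the selected comment roles attached.
#' @export
tidy.sst_feedback <- function(x, ...) {
  dplyr::mutate(
    x$zscores,
    role = dplyr::case_when(
      .data$feature == x$positive_feature ~ "positive",
      .data$feature == x$improve_feature ~ "improve",
      TRUE ~ NA_character_
    )
  )
}

#' @rdname tidy.sst_feedback
#' @export
glance.sst_feedback <- function(x, ...) {
  tibble::tibble(
    overall_score = x$overall_score,
    positive_feature = x$positive_feature,
    improve_feature = x$improve_feature,
    n_features = nrow(x$zscores)
  )
}

#' Radar chart of a feedback report
#'
#' Plots the user's per-feature z-scores against the model-cohort baseline
#' (z = 0) on polar axes — the "comparison with models" panel of the
#' feedback screen.
#'
#' @param object An `sst_feedback`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sst_feedback <- function(object, ...) {
  radar <- tidyr::pivot_longer(object$radar, cols = c("user_z", "model_z"),
                               names_to = "who", values_to = "z")
  radar$who <- ifelse(radar$who == "user_z", "you", "models")
  closed <- dplyr::bind_rows(radar, radar[radar$feature == levels(radar$feature)[1], ])
  ggplot2::ggplot(closed,
                  ggplot2::aes(x = .data$feature, y = .data$z,
                               group = .data$who, colour = .data$who,
                               fill = .data$who)) +
    ggplot2::geom_polygon(alpha = 0.2) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "z-score vs. model cohort", colour = NULL,
                  fill = NULL,
                  title = sprintf("Overall score: %.0f / 100", object$overall_score)) +
    ggplot2::theme_minimal()
}

#' Pre/post rating slope chart
#'
#' One line per participant from the pre- to the post-training rating —
#' the per-participant view behind the mean-improvement statistic.
#'
#' @param ratings Rating tibble (see [read_ratings()]).
#' @return A ggplot.
#' @export
plot_ratings <- function(ratings) {
  long <- tidyr::pivot_longer(ratings, cols = c("pre", "post"),
                              names_to = "phase", values_to = "score")
  long$phase <- factor(long$phase, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$score,
                                     group = .data$id, colour = .data$id)) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "overall narrative skill (1-7)") +
    ggplot2::theme_minimal()
}

#' Read / write a model-cohort feature CSV
#'
#' One row per model speaker, columns named by feature.
#'
#' @param path CSV path.
#' @return `read_cohort()` returns a tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
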