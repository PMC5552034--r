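#' Read a pre/post rating table
#'
#' CSV with columns `id,age,pre,post,followup` (followup may be blank):
#' one row per participant, Likert ratings of overall narrative skill
#' before and after training.
#'
#' @param path CSV path.
#' @param scale Two-element declared rating-scale bounds (default 1-7).
#' @return A validated tibble.
#' @export
read_ratings <- function(path, scale = c(1, 7)) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            id = readr::col_character(),
                            age = readr::col_double(),
                            pre = readr::col_double(),
                            post = readr::col_double(),
                            followup = readr::col_double()
                          ))
  if (anyDuplicated(data$id)) abort("participant ids must be unique")
  in_scale <- function(v) all(is.na(v) | (v >= scale[1] & v <= scale[2]))
  if (!in_scale(data$pre) || !in_scale(data$post) || !in_scale(data$followup)) {
    abort(sprintf("scores outside the declared scale [%g, %g]", scale[1], scale[2]))
  }
  data
}

#' Bundled pre/post rating table of the ten ASD participants
#'
#' The individual trainer ratings (1-7 Likert) of overall narrative skill
#' before and after a single training session, for the ten participants
#' with autism spectrum disorders, with their ages. Loading it and calling
#' [paired_t()] / [cohens_d_pooled()] reproduces the headline pre/post
#' statistics.
#'
#' @return Tibble with columns `id`, `age`, `pre`, `post`, `followup`.
#' @export
#' @examples
#' paired_t(asd_ratings())
asd_ratings <- function() {
  read_ratings(system.file("extdata", "asd_pre_post_ratings.csv",
                           package = "sstcoach"))
}

one_and_two_tail <- function(t_stat, df, tail) {
  p_less <- pt(t_stat, df)
  p_one <- switch(tail,
                  less = p_less,
                  greater = 1 - p_less,
                  two.sided = NA_real_)
  p_two <- 2 * min(p_less, 1 - p_less)
  if (tail == "two.sided") p_one <- p_two
  list(p_one = p_one, p_two = p_two)
}

#' Paired t-test on pre/post scores
#'
#' Computes the paired Student's t on the differences `pre - post`:
#' `t = mean(pre - post) / (sd(pre - post) / sqrt(n))`, df = n - 1, sd with
#' the n-1 denominator. With this sign convention an improvement
#' (post > pre) gives a *negative* t, and the matching one-tailed
#' alternative is `tail = "less"` (the default). Both the one-tailed and
#' two-tailed p-values are always reported.
#'
#' @param data Data frame containing the two score columns.
#' @param pre,post Column names (unquoted or character) of the paired
#'   scores; defaults `pre` and `post`.
#' @param tail `"less"` (improvement), `"greater"`, or `"two.sided"`.
#' @return A one-row tibble: `statistic` (t), `df`, `p_one`, `p_two`,
#'   `tail`, `mean_diff` (pre - post), `sd_diff`, `n`.
#' @export
#' @examples
#' paired_t(asd_ratings())
paired_t <- function(data, pre = "pre", post = "post",
                     tail = c("less", "greater", "two.sided")) {
  tail <- match.arg(tail)
  pre_v <- pull_col(data, rlang::enquo(pre))
  post_v <- pull_col(data, rlang::enquo(post))
  if (length(pre_v) != length(post_v)) abort("pre and post must have equal length")
  if (length(pre_v) < 2) abort("need at least 2 pairs")
  d <- pre_v - post_v
  if (sd(d) == 0) abort("zero variance of paired differences")
  tt <- t.test(pre_v, post_v, paired = TRUE, alternative = tail)
  ps <- one_and_two_tail(unname(tt$statistic), unname(tt$parameter), tail)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_one = ps$p_one, p_two = ps$p_two, tail = tail,
    mean_diff = mean(d), sd_diff = sd(d), n = length(d)
  )
}

#' Two-sample pooled-variance Student's t-test
#'
#' Classical Student's t with pooled variance, df = n_a + n_b - 2, on the
#' difference `mean(a) - mean(b)`. Both tails are always reported.
#'
#' @param data Data frame in long form.
#' @param value,group Columns holding the scores and the two-level group
#'   labels.
#' @param tail Alternative for `mean(a) - mean(b)` with `a` the first
#'   group level: `"less"`, `"greater"`, or `"two.sided"` (default
#'   `"two.sided"`).
#' @return One-row tibble: `statistic`, `df`, `p_one`, `p_two`, `tail`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
#' @examples
#' df <- data.frame(score = c(4, 5, 3, 6, 5, 7),
#'                  grp = rep(c("audio", "audiovisual"), each = 3))
#' two_sample_t(df, score, grp)
two_sample_t <- function(data, value = "value", group = "group",
                         tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  v <- pull_col(data, rlang::enquo(value))
  g <- pull_col(data, rlang::enquo(group))
  g <- factor(g)
  if (nlevels(g) != 2) abort("group must have exactly 2 levels")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 scores")
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) abort("zero pooled variance")
  tt <- t.test(a, b, var.equal = TRUE, alternative = tail)
  ps <- one_and_two_tail(unname(tt$statistic), unname(tt$parameter), tail)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_one = ps$p_one, p_two = ps$p_two, tail = tail,
    mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b)
  )
}

#' Pooled Cohen's d for pre/post scores
#'
#' Standardized mean difference with the pooled-standard-deviation
#' convention over the two score sets:
#' `d = (mean(post) - mean(pre)) / sqrt((var(pre) + var(post)) / 2)`,
#' variances with the n-1 denominator. Positive d means improvement. Note
#' this is the two-group pooled convention, not the d-of-differences.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `d`, `mean_pre`, `mean_post`, `pooled_sd`, `n`.
#' @export
#' @examples
#' cohens_d_pooled(asd_ratings())
cohens_d_pooled <- function(data, pre = "pre", post = "post") {
  pre_v <- pull_col(data, rlang::enquo(pre))
  post_v <- pull_col(data, rlang::enquo(post))
  if (length(pre_v) < 2 || length(post_v) < 2) abort("need at least 2 scores per group")
  pooled_sd <- sqrt((var(pre_v) + var(post_v)) / 2)
  if (pooled_sd == 0) abort("zero pooled standard deviation")
  tibble::tibble(
    d = (mean(post_v) - mean(pre_v)) / pooled_sd,
    mean_pre = mean(pre_v), mean_post = mean(post_v),
    pooled_sd = pooled_sd, n = length(pre_v)
  )
}

#' Pearson correlation between two score columns
#'
#' @param data Data frame.
#' @param x,y Score columns.
#' @return One-row tibble: `r`, `n`, `p_two`.
#' @export
pearson_r <- function(data, x = "x", y = "y") {
  xv <- pull_col(data, rlang::enquo(x))
  yv <- pull_col(data, rlang::enquo(y))
  if (length(xv) != length(yv)) abort("x and y must have equal length")
  if (length(xv) < 3) abort("need at least 3 pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("correlation undefined for constant input")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = length(xv),
                 p_two = ct$p.value)
}

#' Above/below-mean rater agreement
#'
#' Each rater's scores are binarized against that rater's own mean (scores
#' at or above the mean are "high", below are "low"); agreement is the
#' fraction of items assigned the same class by the reference rater and
#' the comparison rater.
#'
#' @param data Data frame.
#' @param reference,rater Score columns for the reference rater and the
#'   compared rater.
#' @return One-row tibble: `agreement` in \[0, 1\], `n`.
#' @export
#' @examples
#' rater_agreement(data.frame(a = 1:4, b = c(1, 1, 4, 4)), a, b)
rater_agreement <- function(data, reference = "reference", rater = "rater") {
  ref <- pull_col(data, rlang::enquo(reference))
  rat <- pull_col(data, rlang::enquo(rater))
  if (length(ref) != length(rat)) abort("score vectors must have equal length")
  if (length(ref) < 2) abort("need at least 2 items")
  cls <- function(v) v >= mean(v)
  tibble::tibble(agreement = mean(cls(ref) == cls(rat)), n = length(ref))
}

#' Pre/post evaluation summary for a rating table
#'
#' One call computing the full pre/post analysis: per-participant
#' differences, the paired one-tailed t-test and pooled Cohen's d.
#'
#' @param ratings Rating tibble (see [read_ratings()]).
#' @param tail Passed to [paired_t()].
#' @return A list: `summary` (one-row tibble with n, means, mean
#'   improvement, t, df, both p-values, d) and `differences` (tibble of
#'   per-participant post - pre).
#' @export
#' @examples
#' evaluate_ratings(asd_ratings())$summary
evaluate_ratings <- function(ratings, tail = "less") {
  tt <- paired_t(ratings, tail = tail)
  d <- cohens_d_pooled(ratings)
  list(
    summary = tibble::tibble(
      n = tt$n, mean_pre = d$mean_pre, mean_post = d$mean_post,
      mean_improvement = d$mean_post - d$mean_pre,
      statistic = tt$statistic, df = tt$df,
      p_one = tt$p_one, p_two = tt$p_two, d = d$d
    ),
    differences = dplyr::mutate(
      dplyr::select(ratings, dplyr::any_of(c("id", "age", "pre", "post"))),
      diff = .data$post - .data$pre
    )
  )
}

# resolve a column given either a bare name or a character scalar
pull_col <- function(data, quo) {
  expr <- rlang::quo_get_expr(quo)
  if (rlang::is_string(expr)) {
    name <- expr
  } else if (rlang::is_symbol(expr)) {
    name <- rlang::as_string(expr)
  } else {
    val <- rlang::eval_tidy(quo)
    if (is.character(val) && length(val) == 1) name <- val
    else return(as.numeric(val))
  }
  if (!name %in% names(data)) abort(paste0("column `", name, "` not found"))
  v <- data[[name]]
  if (is.factor(v) || is.character(v)) v else as.numeric(v)
}
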