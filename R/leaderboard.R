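#' Score one submission against a target's ground truth(s)
#'
#' The competition rule for a single target: every model of the submission
#' is scored against every alternative ground-truth conformation, and the
#' best value is kept — the maximum for TM metrics, the minimum for RMSD.
#' Model/conformation pairs that cannot be scored (e.g. fewer than three
#' residues solved in both) are skipped; if no pair is scorable the target
#' is unscorable.
#'
#' @param submission A [submission_set()].
#' @param solutions A [solution_set()].
#' @param metric One of `"tm_align"`, `"tm_score"`, `"rmsd"`.
#' @return The per-target score (a single number).
#' @export
per_target_score <- function(submission, solutions,
                             metric = c("tm_align", "tm_score", "rmsd")) {
  metric <- match.arg(metric)
  vals <- c()
  for (model in submission$models) {
    for (conf in solutions$conformations) {
      v <- tryCatch(switch(metric,
                           tm_align = tm_align(model, conf)$tm,
                           tm_score = tm_score(model, conf)$tm,
                           rmsd = rmsd_c1(model, conf)),
                    rnascore_unscorable = function(e) NA_real_)
      vals <- c(vals, v)
    }
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort_unscorable(paste0("no scorable model/conformation pair for target ",
                            submission$target_id))
  }
  if (metric == "rmsd") min(vals) else max(vals)
}

#' Assemble a long score table
#'
#' Scores every group's submission on every target and returns the long
#' leaderboard table the aggregation functions consume.
#'
#' @param submissions Nested list: `submissions[[group]][[target_id]]` is a
#'   [submission_set()].
#' @param solutions Named list of [solution_set()]s keyed by target id.
#' @param metric Metric tag as in [per_target_score()].
#' @return A tibble with columns `group`, `target`, `metric`, `value`.
#' @export
score_table <- function(submissions, solutions,
                        metric = c("tm_align", "tm_score", "rmsd")) {
  metric <- match.arg(metric)
  rows <- list()
  for (group in names(submissions)) {
    for (target in names(submissions[[group]])) {
      if (!target %in% names(solutions)) {
        abort_input(paste0("no solution set for target ", target))
      }
      rows[[length(rows) + 1]] <- tibble(
        group = group, target = target, metric = metric,
        value = per_target_score(submissions[[group]][[target]],
                                 solutions[[target]], metric))
    }
  }
  dplyr::bind_rows(rows)
}

#' Mean leaderboard score per group
#'
#' Arithmetic mean of the per-target scores over the targets each group
#' was scored on (only present entries contribute).
#'
#' @param scores Long score table with columns `group`, `target`, `value`
#'   (as from [score_table()]).
#' @return A tibble `group`, `n_targets`, `mean_value`, sorted by group.
#' @export
leaderboard_mean <- function(scores) {
  check_scores(scores)
  scores |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_targets = dplyr::n(),
                     mean_value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Combine each group's two selected algorithms
#'
#' Per target, the better of the two algorithms' per-target scores is
#' taken (max for TM metrics, min for RMSD), then averaged over targets.
#'
#' @param scores Long table with columns `group`, `algorithm`, `target`,
#'   `value`: per-target scores for each of a group's (up to two) selected
#'   algorithms.
#' @param metric Metric tag; decides the per-target direction.
#' @return A tibble `group`, `n_targets`, `mean_value`.
#' @export
best_of_two <- function(scores, metric = c("tm_align", "tm_score", "rmsd")) {
  metric <- match.arg(metric)
  if (!all(c("group", "algorithm", "target", "value") %in% names(scores))) {
    abort_input("best_of_two needs columns group, algorithm, target, value")
  }
  better <- if (metric == "rmsd") min else max
  scores |>
    dplyr::group_by(.data$group, .data$target) |>
    dplyr::summarise(value = better(.data$value), .groups = "drop") |>
    leaderboard_mean()
}

#' Two-pass outlier-trimmed Z-scores
#'
#' Standardizes scores within each target across groups. Pass one computes
#' `z = (s - mean) / sd` over all groups; pass two recomputes mean and sd
#' after removing groups whose pass-one z fell below the trim threshold,
#' and the final z of every group — including the trimmed ones — uses the
#' pass-two statistics. RMSD scores are negated before standardization so
#' that larger z is uniformly better. If the pass-two sd collapses to
#' zero, every z for that target is 0.
#'
#' @param scores Long score table (`group`, `target`, `value`).
#' @param metric Metric tag; `"rmsd"` flips the sign before standardizing.
#' @param trim Trim threshold for pass one (default -2).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A tibble `group`, `target`, `z`, `trimmed` (whether the group
#'   was excluded from the pass-two statistics for that target).
#' @export
zscores <- function(scores, metric = c("tm_align", "tm_score", "rmsd"),
                    trim = -2, sd_type = c("sample", "population")) {
  metric <- match.arg(metric)
  sd_type <- match.arg(sd_type)
  check_scores(scores)
  sdev <- function(v) {
    if (length(v) < 2) return(0)
    s <- sd(v)
    if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
    s
  }
  one_target <- function(df) {
    v <- if (metric == "rmsd") -df$value else df$value
    if (length(v) < 2) abort_input("zscores needs at least 2 groups per target")
    s1 <- sdev(v)
    z1 <- if (s1 > 0) (v - mean(v)) / s1 else rep(0, length(v))
    keep <- z1 >= trim
    v2 <- v[keep]
    s2 <- sdev(v2)
    z <- if (s2 > 0) (v - mean(v2)) / s2 else rep(0, length(v))
    tibble(group = df$group, target = df$target, z = z, trimmed = !keep)
  }
  scores |>
    dplyr::group_by(.data$target) |>
    dplyr::group_split() |>
    purrr::map(one_target) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$target, .data$group)
}

#' Mean Z-score per group
#'
#' @param z Output of [zscores()].
#' @return A tibble `group`, `mean_z`.
#' @export
zscore_mean <- function(z) {
  z |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Rank groups under several metrics
#'
#' Sorts groups by mean value per metric — descending for TM and Z
#' metrics, ascending for RMSD — with competition ranking for ties (tied
#' groups share the minimum rank; the next group skips ranks).
#'
#' @param means Long table with columns `group`, `metric`, `mean_value`,
#'   one row per group x metric.
#' @return The input with a `rank` column added.
#' @export
rank_groups <- function(means) {
  if (!all(c("group", "metric", "mean_value") %in% names(means))) {
    abort_input("rank_groups needs columns group, metric, mean_value")
  }
  means |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(rank = {
      v <- if (unique(.data$metric) == "rmsd") .data$mean_value else -.data$mean_value
      as.integer(rank(v, ties.method = "min"))
    }) |>
    dplyr::ungroup()
}

#' Paired one-sided comparison of two groups
#'
#' Tests whether group `a` outperforms group `b` with a paired one-sided
#' t-test on the per-target differences (a - b, alternative "greater"),
#' over the targets both groups were scored on. With zero-variance
#' differences the test degenerates: p is 0, 1 or 0.5 according to the
#' sign of the (constant) mean difference.
#'
#' @param scores Long score table (`group`, `target`, `value`).
#' @param group_a,group_b Group identifiers.
#' @return One-row tibble: `group_a`, `group_b`, `n_targets`, `statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(scores, group_a, group_b) {
  check_scores(scores)
  a <- scores[scores$group == group_a, c("target", "value")]
  b <- scores[scores$group == group_b, c("target", "value")]
  j <- dplyr::inner_join(a, b, by = "target", suffix = c("_a", "_b"))
  if (nrow(j) < 3) abort_input("need at least 3 shared targets to compare groups")
  d <- j$value_a - j$value_b
  n <- length(d)
  if (sd(d) < 1e-12) {
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    stat <- if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else 0
  } else {
    stat <- mean(d) / (sd(d) / sqrt(n))
    p <- pt(stat, df = n - 1, lower.tail = FALSE)
  }
  tibble(group_a = group_a, group_b = group_b, n_targets = n,
         statistic = stat, p_value = p)
}

check_scores <- function(scores) {
  if (!all(c("group", "target", "value") %in% names(scores))) {
    abort_input("score table needs columns group, target, value")
  }
  if (anyNA(scores$value)) abort_input("score table contains missing values")
  invisible(scores)
}
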