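#' Plot the per-pair distance profile of a TM result
#'
#' Post-superposition distance of every aligned pair along the reference,
#' with the d0 scale drawn as a dashed line: pairs below it contribute
#' more than half of their maximal TM weight.
#'
#' @param object A `tm_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tm_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_pos, y = .data$distance)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$d0, linetype = "dashed") +
    ggplot2::labs(x = "reference position", y = "distance (Å)",
                  title = sprintf("%s: TM = %.3f (Lref = %d, d0 = %.2f Å)",
                                  object$mode, object$tm, object$lref,
                                  object$d0)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a long score table
#'
#' Groups by targets, tile fill by score, with the 0.45 fold threshold at
#' the midpoint of the fill scale for TM metrics.
#'
#' @param scores Long table (`group`, `target`, `value`), as from
#'   [score_table()].
#' @param metric Metric tag used for labeling and the fill midpoint.
#' @return A ggplot.
#' @export
plot_leaderboard <- function(scores, metric = "tm_align") {
  check_scores(scores)
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$target, y = .data$group,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::labs(x = "target", y = "group", fill = metric) +
    ggplot2::theme_minimal()
  if (metric != "rmsd") {
    p <- p + ggplot2::scale_fill_gradient2(midpoint = 0.45,
                                           low = "steelblue", mid = "white",
                                           high = "firebrick")
  }
  p
}

#' Plot a greedy ensemble-selection trace
#'
#' Diversity and distance-to-priors of the chosen candidate at each greedy
#' step (anchor steps carry no score and are marked).
#'
#' @param trace Output of [select_ensemble()].
#' @return A ggplot.
#' @export
plot_ensemble_trace <- function(trace) {
  df <- tidyr::pivot_longer(
    trace[, c("step", "source", "anchor", "diversity", "distance_to_priors")],
    c("diversity", "distance_to_priors"),
    names_to = "component", values_to = "rmsd")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$rmsd,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$anchor), size = 2,
                        na.rm = TRUE) +
    ggplot2::labs(x = "selection step", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
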