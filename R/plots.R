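#' Plot a Bayes factor comparison
#'
#' Bar chart of log Bayes factors against the unconstrained model, ordered by
#' rank, with Monte-Carlo error bars where the encompassing step contributes
#' sampling noise.
#'
#' @param object An `rkn_bf` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rkn_bf <- function(object, ...) {
  d <- object$results |>
    dplyr::mutate(model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_bf, y = .data$model)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(xmin = .data$log_bf - 2 * .data$mc_error,
                   xmax = .data$log_bf + 2 * .data$mc_error),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(log ~ BF ~ vs ~ M[u]), y = NULL,
      title = paste("Winner:", object$winner)
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean response proportions by condition
#'
#' The standard descriptive display for this paradigm: mean remember, know
#' and new response proportions, one panel per item status, lexicality on the
#' x-axis. A crossover of the remember and know lines for old items is the
#' dual-process signature; parallel lines indicate a global response bias.
#'
#' @param counts A count table from [aggregate_counts()].
#' @return A ggplot object.
#' @export
plot_response_proportions <- function(counts) {
  d <- proportion_table(counts) |>
    tidyr::pivot_longer(c("remember", "know", "new"),
                        names_to = "response", values_to = "proportion") |>
    dplyr::mutate(
      response = factor(.data$response, levels = rkn_response_levels()),
      status = factor(.data$status, levels = c("old", "new"),
                      labels = c("old items", "lures"))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lexicality, y = .data$proportion,
                                  colour = .data$response,
                                  group = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~status) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean response proportion", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot individual scaled differences, nonwords against words
#'
#' Scatter plot of each participant's scaled difference for nonwords against
#' words, one panel per item status, with the identity line. Points above the
#' diagonal in the old-item panel indicate the dual-process pattern for that
#' participant; a tight positive correlation along the diagonal indicates a
#' global remember-vs-know bias instead.
#'
#' @param counts A count table from [aggregate_counts()].
#' @return A ggplot object.
#' @export
plot_scaled_differences <- function(counts) {
  d <- scaled_differences(counts) |>
    dplyr::select("participant", "status", "lexicality", "y") |>
    tidyr::pivot_wider(names_from = "lexicality", values_from = "y") |>
    dplyr::mutate(status = factor(.data$status, levels = c("old", "new"),
                                  labels = c("old items", "lures")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$word, y = .data$nonword)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~status) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "scaled difference, words",
                  y = "scaled difference, nonwords") +
    ggplot2::theme_minimal()
}

#' Plot model-recovery rates
#'
#' @param object An `rkn_recovery` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rkn_recovery <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = factor(.data$I), y = .data$rate,
                               fill = .data$winner)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "participants", y = "winning rate", fill = "winner") +
    ggplot2::theme_minimal()
}
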