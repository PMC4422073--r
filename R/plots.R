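#' Quantile plot of a significance-analysis fit
#'
#' Observed against expected ordered statistics with the selected delta
#' band; called genes are highlighted.
#'
#' @param object A `sam_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sam_fit
#' @export
autoplot.sam_fit <- function(object, ...) {
  td <- tidy(object)
  delta <- object$selection$delta
  ggplot2::ggplot(td, ggplot2::aes(x = .data$d_expected, y = .data$d,
                                   colour = .data$called)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = c(-delta, delta),
                         linetype = 3, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "expected ordered statistic",
                  y = "observed statistic",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Step-function survival curves
#'
#' @param object A `km_fit` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot of right-continuous survival steps per group.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- object %>%
    dplyr::distinct(.data$group) %>%
    mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start,
                         object[, c("group", "time", "survival")]) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival") +
    ggplot2::theme_minimal()
}

#' Score distribution with the median split
#'
#' @param scores A [median_split()] tibble.
#' @return A ggplot histogram coloured by group.
#' @export
plot_score_split <- function(scores) {
  ggplot2::ggplot(scores[!is.na(scores$score), ],
                  ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 30, position = "identity",
                            alpha = 0.7) +
    ggplot2::geom_vline(xintercept = median(scores$score, na.rm = TRUE),
                        linetype = 2) +
    ggplot2::labs(x = "centroid score", y = "patients") +
    ggplot2::theme_minimal()
}
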