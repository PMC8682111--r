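# ggplot2 displays for each result type

#' Plot a cost-effectiveness acceptability curve
#'
#' Probability that each strategy is cost-effective as a function of
#' willingness to pay per composite outcome avoided.
#'
#' @param object A [ceac()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"wtp",
                              names_to = "strategy", values_to = "probability",
                              names_prefix = "prob_")
  ggplot2::ggplot(long, ggplot2::aes(.data$wtp, .data$probability,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = ",", scientific = FALSE)) +
    ggplot2::labs(x = "Willingness to pay (BRL per outcome avoided)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PSA draws on the cost-effectiveness plane
#'
#' Incremental effectiveness against incremental cost, one point per
#' Monte Carlo draw.
#'
#' @param object A [run_psa()] result.
#' @param wtp Optional willingness-to-pay threshold drawn as a line
#'   through the origin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, wtp = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$delta_eff, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental effectiveness (outcomes avoided)",
                  y = "Incremental cost (BRL)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0, colour = "grey40")
  }
  p
}

#' Tornado plot of the one-way sensitivity analysis
#'
#' Horizontal bars spanning each parameter's low/high ICER, widest
#' first, with the base-case ICER as a reference line.
#'
#' @param object A [one_way_dsa()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsa_result <- function(object, ...) {
  df <- as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_min, xend = .data$icer_max,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"), linetype = 2) +
    ggplot2::labs(x = "ICER (BRL per outcome avoided)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Markov cohort trace
#'
#' State occupancy across cycles.
#'
#' @param object A [run_trace()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$cycle, .data$occupancy,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (years)", y = "State occupancy", colour = NULL) +
    ggplot2::theme_minimal()
}
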