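# Plot helpers (ggplot2, optional).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot a visual predictive check
#'
#' Observed 5th/50th/95th percentiles overlaid on the simulation-based 95%
#' confidence envelopes per bin.
#'
#' @param x a [vpc()] result
#' @param log_y log-scale the concentration axis
#' @return a ggplot object
#' @export
plot_vpc <- function(x, log_y = FALSE) {
  .need_ggplot()
  b <- x$bins
  g <- ggplot2::ggplot(b, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p5_lo, ymax = sim_p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p95_lo, ymax = sim_p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo, ymax = sim_p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p95), linetype = 2) +
    ggplot2::labs(x = "time after first CPG2 dose (h)",
                  y = sprintf("%s concentration", x$analyte))
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}

#' Plot RMSE by sampling subset
#'
#' Bar chart of the 48-h forecast RMSE for every sampling subset, with
#' subsets containing the 24-h point highlighted.
#'
#' @param x an [evaluate_all_subsets()] report
#' @return a ggplot object
#' @export
plot_lss <- function(x) {
  .need_ggplot()
  d <- as.data.frame(x)
  d$subset <- factor(d$subset, levels = d$subset)
  ggplot2::ggplot(d, ggplot2::aes(x = subset, y = rmse,
                                  fill = contains_24h)) +
    ggplot2::geom_col(colour = "black") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               name = "includes 24 h") +
    ggplot2::labs(x = NULL, y = "RMSE of 48-h forecast (umol/L)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
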