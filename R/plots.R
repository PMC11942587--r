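#' Plot helpers (optional, require ggplot2)
#'
#' Thin figure layers over the data the analysis writes anyway: the
#' cost-effectiveness plane of a PSA cloud (with the willingness-to-pay
#' line), the acceptability curves, and the tornado diagram. Each
#' returns a ggplot object.
#'
#' @param psa a `cea_psa`.
#' @param lambda willingness-to-pay for the threshold line.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa, lambda = NULL) {
  require_ggplot()
  p <- ggplot2::ggplot(psa$outcomes,
                       ggplot2::aes(x = .data$effect, y = .data$cost,
                                    colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::labs(x = "Effect (QALY)", y = "Cost (RMB)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(lambda))
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0,
                                  linetype = "dashed")
  p
}

#' @rdname plot_ce_plane
#' @param curves output of [ceac()].
#' @export
plot_ceac <- function(curves) {
  require_ggplot()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (RMB/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ce_plane
#' @param bars output of [tornado()].
#' @export
plot_tornado <- function(bars) {
  require_ggplot()
  bars$parameter <- factor(bars$parameter, levels = rev(bars$parameter))
  ggplot2::ggplot(bars, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Outcome (incremental NMB, RMB)", y = NULL,
                  title = "Tornado diagram") +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_ceatree("ggplot2 is required for plotting helpers",
                  "ceatree_dependency_error")
}
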