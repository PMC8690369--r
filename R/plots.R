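#' Plot Aalen-Johansen cumulative incidence curves
#'
#' One right-continuous step curve per prior-relapse stratum: probability of
#' having experienced the next relapse as a function of time since the last
#' episode's end.
#'
#' @param object A [cumulative_incidence()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relapse_cif
#' @export
autoplot.relapse_cif <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = time, y = cif_relapse,
                                       colour = factor(stratum))) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(x = "Years since end of last relapse episode",
                  y = "Cumulative incidence of next relapse",
                  colour = "Prior relapses") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot hazard ratios by number of prior relapses
#'
#' Forest-style display of the Cox hazard ratios (and Wald confidence
#' intervals) for each prior-relapse stratum versus zero prior relapses,
#' on a log scale.
#'
#' @param object A [fit_cox()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relapse_cox
#' @export
autoplot.relapse_cox <- function(object, ...) {
  ggplot2::ggplot(object$strata,
                  ggplot2::aes(x = factor(stratum), y = hr)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = conf_low, ymax = conf_high),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Number of prior relapses",
                  y = "Hazard ratio vs 0 prior relapses (log scale)") +
    ggplot2::theme_minimal()
}

#' @export
plot.relapse_cif <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.relapse_cox <- function(x, ...) print(autoplot(x, ...))
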