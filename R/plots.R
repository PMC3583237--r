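## ggplot2 methods ------------------------------------------------------------

#' Plot a dose-response sweep
#'
#' @param object A `pdc_dose_response`.
#' @param ... Unused.
#' @return A ggplot: `R` against the control pool on a log axis, with the
#'   asymptote (if known) as a dashed reference line.
#' @method autoplot pdc_dose_response
#' @export
autoplot.pdc_dose_response <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value, y = .data$R)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(object$control[1], " (uM)"),
                  y = "phosphorylated fraction R",
                  title = paste0("Dose-response (", object$method[1], ")")) +
    ggplot2::theme_minimal()
  rinf <- attr(object, "R_inf")
  if (!is.null(rinf) && is.finite(rinf)) {
    p <- p + ggplot2::geom_hline(yintercept = rinf, linetype = "dashed")
  }
  p
}

#' Plot a trajectory or transient scenario
#'
#' @param object A `pdc_trajectory` / `pdc_transient`.
#' @param ... Unused.
#' @return A ggplot of `R(t)`.
#' @method autoplot pdc_trajectory
#' @export
autoplot.pdc_trajectory <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)[c("time", "R")]),
                  ggplot2::aes(x = .data$time, y = .data$R)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "phosphorylated fraction R") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D parameter scan
#'
#' @param object A `pdc_scan`.
#' @param ... Unused.
#' @return A ggplot heat map of the metric with the threshold mask contour.
#' @method autoplot pdc_scan
#' @export
autoplot.pdc_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)[c("value1", "value2", "metric")]),
                  ggplot2::aes(x = .data$value1, y = .data$value2,
                               fill = .data$metric)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$axis1[1], y = object$axis2[1],
                  fill = attr(object, "metric_name")) +
    ggplot2::theme_minimal()
}
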