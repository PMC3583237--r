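## broom-style verbs ----------------------------------------------------------

#' Tidy a Hill-number result
#'
#' @param x A `pdc_hill` object.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`term`, `estimate`).
#' @method tidy pdc_hill
#' @export
tidy.pdc_hill <- function(x, ...) {
  tibble(term = names(x), estimate = as.numeric(x[1, ]))
}

#' @rdname tidy.pdc_hill
#' @method glance pdc_hill
#' @export
glance.pdc_hill <- function(x, ...) {
  tibble(nH = x$nH, R_inf = x$R_inf, Kt10 = x$Kt10, Kt90 = x$Kt90)
}

#' Tidy a dose-response sweep
#'
#' @param x A `pdc_dose_response`.
#' @param ... Unused.
#' @return The sweep as a plain tibble.
#' @method tidy pdc_dose_response
#' @export
tidy.pdc_dose_response <- function(x, ...) {
  as_tibble(unclass(x)[c("control", "value", "R", "method")])
}

#' @rdname tidy.pdc_dose_response
#' @method glance pdc_dose_response
#' @export
glance.pdc_dose_response <- function(x, ...) {
  tibble(control = x$control[1], method = x$method[1], n = nrow(x),
         R_min = min(x$R, na.rm = TRUE), R_max = max(x$R, na.rm = TRUE),
         R_inf = attr(x, "R_inf") %||% NA_real_,
         n_failed = sum(!is.finite(x$R)))
}

#' Tidy a numeric steady state
#'
#' @param x A `pdc_steady_state`.
#' @param ... Unused.
#' @return Long tibble of species concentrations.
#' @method tidy pdc_steady_state
#' @export
tidy.pdc_steady_state <- function(x, ...) {
  sp <- setdiff(names(x), c("R", "residual", "converged"))
  tibble(species = sp, concentration = as.numeric(x[1, sp]))
}

#' @rdname tidy.pdc_steady_state
#' @method glance pdc_steady_state
#' @export
glance.pdc_steady_state <- function(x, ...) {
  tibble(R = x$R, residual = x$residual, converged = x$converged)
}

#' Glance at a transient scenario
#'
#' @param x A `pdc_transient`.
#' @param ... Unused.
#' @return One-row tibble with the scenario's peak annotation.
#' @method glance pdc_transient
#' @export
glance.pdc_transient <- function(x, ...) {
  dplyr::mutate(attr(x, "peak"),
                scenario = attr(x, "scenario"),
                rate = attr(x, "rate"),
                switch_time = attr(x, "switch_time"))
}
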