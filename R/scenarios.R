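## Transient phosphoinositide-regulation scenarios ----------------------------
##
## Two mechanisms for a transient pulse of phosphorylated lipid on a
## maturing endosome:
##  (i) recruitment: the kinase arrives on the membrane at a constant rate
##      (total kinase Kt(t) = rate * t), the phosphatase level is fixed, and
##      the kinase-phosphatase complex acts as a phosphatase -- the pulse is
##      the bell-shaped dose-response traversed in time;
## (ii) trigger: fixed enzyme pools, and at a set time a signal switches the
##      complex's activity from kinase to phosphatase.

#' Linear kinase-recruitment transient
#'
#' Integrates the phosphatase-active extended model with a constant source
#' term on free kinase, so the total kinase grows linearly,
#' `Kt(t) = Kt(0) + rate * t` (newly recruited enzyme arrives unbound).
#' Substrate and phosphatase conservation hold exactly; the kinase total is
#' checked against the linear ramp.
#'
#' @param params A phosphatase-active `pdc_params` row; `params$Kt` is the
#'   initial total kinase (the shipped `fig9_recruitment` set starts at 0).
#' @param rate Recruitment rate (uM/s).
#' @param t_end Simulated window (s).
#' @param n Number of output samples.
#' @return A `pdc_transient` tibble (trajectory plus peak annotations; see
#'   [peak_time()]).
#' @export
simulate_recruitment <- function(params, rate, t_end, n = 2000) {
  assert_params(params)
  if (params$variant != "complex_P_active") {
    abort("recruitment scenario uses the phosphatase-active variant")
  }
  if (rate < 0) abort("recruitment rate must be >= 0")
  traj <- pdc_integrate(params, times = seq(0, t_end, length.out = n),
                        recruit = rate)
  .as_transient(traj, scenario = "recruitment", rate = rate)
}

#' Triggered kinase-to-phosphatase activity switch
#'
#' Integrates the kinase-active extended model up to `switch_time`, then
#' restarts the integration from the reached state with the complex's
#' activity switched to the phosphatase arm.  By default (`bound =
#' "drain"`) substrate bound through the deactivated kinase arm (`SPK`)
#' keeps its dissociation rate and unbinds gradually; `bound = "release"`
#' frees it instantaneously at the switch.
#'
#' @param params Pre-switch (kinase-active) `pdc_params` row.
#' @param post Named list of post-switch phosphatase-arm rates
#'   (`lambda3`, `lambda_m3`, `k3`).
#' @param switch_time Switch time (s), within the window.
#' @param t_end Simulated window (s).
#' @param bound `"drain"` or `"release"` (fate of `SPK` at the switch).
#' @param n Number of output samples.
#' @return A `pdc_transient` tibble.
#' @export
simulate_trigger <- function(params, post, switch_time, t_end,
                             bound = c("drain", "release"), n = 2000) {
  bound <- match.arg(bound)
  assert_params(params)
  if (switch_time <= 0) abort("switch_time must be > 0")
  if (switch_time >= t_end) {
    ## switch never fires inside the window: pure pre-switch transient
    traj <- pdc_integrate(params, times = seq(0, t_end, length.out = n))
    return(.as_transient(traj, scenario = "trigger", switch_time = switch_time))
  }
  t1 <- seq(0, switch_time, length.out = max(50, ceiling(n * switch_time / t_end)))
  pre <- pdc_integrate(params, times = t1)
  y_switch <- setNames(as.numeric(pre[nrow(pre), pdc_species(params)]),
                       pdc_species(params))
  p2 <- params
  for (nm in names(post)) p2[[nm]] <- post[[nm]]
  ## deactivate the kinase arm: no new binding, no catalysis; keep lambda_m4
  p2$lambda4 <- 0; p2$k4 <- 0
  p2$variant <- "complex_P_active"
  p2 <- suppressWarnings(validate_variant(p2))
  if (bound == "release") {
    y_switch["S"] <- y_switch["S"] + y_switch["SPK"]
    y_switch["PK"] <- y_switch["PK"] + y_switch["SPK"]
    y_switch["SPK"] <- 0
  }
  t2 <- seq(switch_time, t_end, length.out = max(50, ceiling(n * (1 - switch_time / t_end))))
  post_traj <- pdc_integrate(p2, times = t2, y0 = y_switch)
  traj <- dplyr::bind_rows(pre[, c("time", pdc_species(params), "R")],
                           post_traj[-1, c("time", pdc_species(params), "R")])
  attr(traj, "params") <- params
  class(traj) <- c("pdc_trajectory", class(traj))
  .as_transient(traj, scenario = "trigger", switch_time = switch_time)
}

.as_transient <- function(traj, scenario, rate = NA_real_, switch_time = NA_real_) {
  pk <- peak_time(traj)
  attr(traj, "scenario") <- scenario
  attr(traj, "rate") <- rate
  attr(traj, "switch_time") <- switch_time
  attr(traj, "peak") <- pk
  class(traj) <- unique(c("pdc_transient", class(traj)))
  traj
}

#' Peak of a transient trajectory
#'
#' Argmax of `R(t)` with three-point parabolic refinement on the sampled
#' trajectory.  A maximum at the window end is flagged (`peak = FALSE`):
#' the trajectory is still rising and the window should be extended.
#'
#' @param traj A `pdc_trajectory`/`pdc_transient` tibble.
#' @return One-row tibble `peak_time`, `peak_R`, `peak` (logical: interior
#'   maximum), `R_end`.
#' @export
peak_time <- function(traj) {
  i <- which.max(traj$R)
  interior <- i > 1 && i < nrow(traj)
  if (interior) {
    ## parabolic refinement in linear time
    tt <- traj$time[(i - 1):(i + 1)]; yy <- traj$R[(i - 1):(i + 1)]
    d1 <- (yy[3] - yy[1]) / (tt[3] - tt[1])
    d2 <- ((yy[3] - yy[2]) / (tt[3] - tt[2]) - (yy[2] - yy[1]) / (tt[2] - tt[1])) /
      ((tt[3] - tt[1]) / 2)
    t_pk <- if (is.finite(d2) && d2 < 0) min(max(tt[2] - d1 / d2, tt[1]), tt[3]) else tt[2]
    r_pk <- if (is.finite(d2) && d2 < 0) yy[2] - d1^2 / (2 * d2) else yy[2]
  } else {
    warn("maximum at window boundary; not an interior peak")
    t_pk <- traj$time[i]; r_pk <- traj$R[i]
  }
  tibble(peak_time = t_pk, peak_R = r_pk, peak = interior,
         R_end = traj$R[nrow(traj)])
}
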