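## Dose-response sweeps and derived metrics -----------------------------------

.default_grid <- function(params, control, n = 200, span = c(1e-2, 1e3)) {
  ref <- params[[control]]
  if (!is.finite(ref) || ref <= 0) ref <- 1
  10^seq(log10(span[1] * ref), log10(span[2] * ref), length.out = n)
}

.set_pool <- function(params, control, value) {
  params[[control]] <- value
  params
}

#' Steady-state dose-response sweep
#'
#' Computes the phosphorylated fraction `R` at steady state along a
#' log-spaced grid of one control pool (`Kt`, `Pt` or `St`).  Backends:
#' `"analytic"` (exact cubic; basic variant only), `"ode"` (numeric steady
#' state of the full kinetics, with continuation of the state along the
#' sweep) and `"tqssa"` (reduced model; phosphatase-active variant, `Kt`
#' control).  A backend failure at a grid point yields `NA` for that point
#' and the sweep continues.
#'
#' The attached asymptote `R_inf` is the exact large-`Kt` limit for the
#' basic variant and the parameter-substituted limit of
#' [r_inf_extended()] for the phosphatase-active variant.
#'
#' @param params A `pdc_params` row.
#' @param control `"Kt"`, `"Pt"` or `"St"`.
#' @param grid Control values (uM); default 200 log-spaced points spanning
#'   `[1e-2, 1e3]` times the fixture's reference value.
#' @param method `"analytic"`, `"ode"` or `"tqssa"`.
#' @param n Grid size when `grid` is NULL.
#' @return A `pdc_dose_response` tibble: `control`, `value`, `R`, `method`.
#' @examples
#' dr <- dose_response(pdc_fixture("fig5a_basic"), control = "Kt", n = 50)
#' hill_number_numeric(dr)
#' @export
dose_response <- function(params, control = c("Kt", "Pt", "St"),
                          grid = NULL, method = c("analytic", "ode", "tqssa"),
                          n = 200) {
  control <- match.arg(control)
  method <- match.arg(method)
  assert_params(params)
  if (method == "analytic" && params$variant != "basic") {
    abort("analytic backend requires the basic variant")
  }
  if (method == "tqssa" && control != "Kt") {
    abort("tqssa backend supports Kt sweeps")
  }
  grid <- sort(grid %||% .default_grid(params, control, n))
  if (any(grid <= 0)) abort("grid values must be positive")

  if (method == "analytic") {
    R <- vapply(grid, function(v) {
      p <- .set_pool(params, control, v)
      tryCatch(r_from_sk(solve_sk(p), p), error = function(e) NA_real_)
    }, numeric(1))
  } else if (method == "tqssa") {
    R <- tqssa_steady_state(params, grid)$R
  } else {
    y_prev <- NULL; v_prev <- NULL
    R <- vapply(seq_along(grid), function(i) {
      p <- .set_pool(params, control, grid[i])
      y0 <- pdc_state(p)
      if (!is.null(y_prev)) {
        y0 <- y_prev
        free <- c(Kt = "K", Pt = "P", St = "S")[[control]]
        y0[free] <- max(y0[free] + (grid[i] - v_prev), 0)
      }
      ss <- tryCatch(steady_state(p, y0 = y0), error = function(e) NULL)
      if (is.null(ss)) return(NA_real_)
      y_prev <<- setNames(as.numeric(ss[1, pdc_species(p)]), pdc_species(p))
      v_prev <<- grid[i]
      ss$R
    }, numeric(1))
  }

  R_inf <- NA_real_
  if (control == "Kt") {
    R_inf <- tryCatch({
      if (params$variant == "basic") sk_inf_kt(params)$R_inf
      else if (params$variant == "complex_P_active") r_inf_extended(params)
      else NA_real_
    }, error = function(e) NA_real_)
  }
  out <- tibble(control = control, value = grid, R = R, method = method)
  attr(out, "params") <- params
  attr(out, "R_inf") <- R_inf
  class(out) <- c("pdc_dose_response", class(out))
  out
}

#' Large-Kt asymptote of the phosphatase-active extended model
#'
#' At saturating kinase essentially no free phosphatase remains, so the
#' system reduces to a basic cycle in which the PK complex plays the
#' phosphatase: substituting the complex arm's rates (`lambda3`,
#' `lambda_m3`, `k3`) for the phosphatase arm's in the basic-cycle
#' asymptote gives the limit (effective `alpha = k2/k3`, `M1 -> M3`).
#'
#' @param params A phosphatase-active `pdc_params` row with `k3 > 0`.
#' @return `R_inf` (dimensionless).
#' @export
r_inf_extended <- function(params) {
  assert_params(params)
  if (params$variant != "complex_P_active") {
    abort("parameter-substituted asymptote applies to the phosphatase-active variant")
  }
  if (params$k3 <= 0) abort("k3 must be > 0")
  sub <- params
  sub$lambda1 <- params$lambda3
  sub$lambda_m1 <- params$lambda_m3
  sub$k1 <- params$k3
  sub[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
  sub$variant <- "basic"
  sk_inf_kt(sub)$R_inf
}

#' Hill number from a numerically computed dose-response curve
#'
#' Applies the response-coefficient formula `nH = log(81)/log(Kt90/Kt10)`
#' to a sweep, with the 10%/90% levels taken relative to the curve's own
#' plateau `R_inf`.  The crossings are located by monotone interpolation in
#' log-control space.
#'
#' @param curve A `pdc_dose_response` over `Kt` (monotone on the analyzed
#'   segment).
#' @param R_inf Plateau; defaults to the curve's attached asymptote.
#' @return A `pdc_hill` one-row tibble (`Kt10`, `Kt90`, `nH`, ...).
#' @export
hill_number_numeric <- function(curve, R_inf = NULL) {
  R_inf <- R_inf %||% attr(curve, "R_inf")
  if (is.null(R_inf) || !is.finite(R_inf)) abort("R_inf unavailable; supply it")
  ok <- is.finite(curve$R)
  v <- curve$value[ok]; R <- curve$R[ok]
  imax <- which.max(R)
  if (max(R) > R[length(R)] + 0.01 * R_inf && imax < length(R)) {
    abort("curve is non-monotone (bell-shaped); use bell_metrics_kt() instead")
  }
  if (max(R) < 0.9 * R_inf) {
    abort("plateau not reached on grid: extend the sweep to larger control values")
  }
  seg <- seq_len(imax)
  vi <- v[seg]; Ri <- cummax(R[seg])   # enforce monotonicity against roundoff
  cross <- function(level) {
    if (level <= Ri[1]) abort("grid does not reach below the 10% level; extend downwards")
    j <- max(which(Ri < level))
    exp(approx(x = Ri[j:(j + 1)], y = log(vi[j:(j + 1)]), xout = level)$y)
  }
  k10 <- cross(0.1 * R_inf); k90 <- cross(0.9 * R_inf)
  out <- tibble(R_inf = R_inf, R10 = 0.1 * R_inf, R90 = 0.9 * R_inf,
                SK10 = NA_real_, SK90 = NA_real_, Kt10 = k10, Kt90 = k90,
                nH = log(81) / log(k90 / k10))
  class(out) <- c("pdc_hill", class(out))
  out
}

#' Hill-function fit to a dose-response curve
#'
#' Least-squares fit of `R = Rmax * v^n / (K^n + v^n)` to the sweep; used as
#' a cross-check on the response-coefficient Hill number (the two agree to
#' within a few percent on sigmoidal curves).
#'
#' @param curve A `pdc_dose_response` (monotone).
#' @return One-row tibble `Rmax`, `K`, `nH`.
#' @export
hill_fit <- function(curve) {
  ok <- is.finite(curve$R)
  d <- data.frame(v = curve$value[ok], R = curve$R[ok])
  rmx <- max(d$R)
  k0 <- exp(approx(d$R, log(d$v), xout = rmx / 2, ties = "ordered")$y)
  fit <- nls(R ~ Rmax * v^n / (K^n + v^n), data = d,
             start = list(Rmax = rmx, K = k0, n = 1.5),
             control = nls.control(maxiter = 500, warnOnly = TRUE))
  co <- coef(fit)
  tibble(Rmax = unname(co["Rmax"]), K = unname(co["K"]), nH = unname(co["n"]))
}

## three-point parabolic refinement of a discrete maximum in log-x space
.refine_peak <- function(x, y, i) {
  if (i == 1 || i == length(x)) return(list(x = x[i], y = y[i]))
  lx <- log(x[(i - 1):(i + 1)]); yy <- y[(i - 1):(i + 1)]
  d1 <- (yy[3] - yy[1]) / (lx[3] - lx[1])
  d2 <- ((yy[3] - yy[2]) / (lx[3] - lx[2]) - (yy[2] - yy[1]) / (lx[2] - lx[1])) /
    ((lx[3] - lx[1]) / 2)
  if (!is.finite(d2) || d2 >= 0) return(list(x = x[i], y = y[i]))
  lxs <- lx[2] - d1 / d2
  lxs <- min(max(lxs, lx[1]), lx[3])
  list(x = exp(lxs), y = yy[2] - d1^2 / (2 * d2))
}

#' Bell-shape metrics of a Kt sweep
#'
#' Locates the maximum of `R` over the sweep (parabolic refinement in
#' log-Kt) and reports `Rmax / R_inf`; a ratio above one signals a
#' bell-shaped (non-monotonic) response.  A maximum on the grid boundary is
#' flagged rather than silently refined.
#'
#' @param curve A `pdc_dose_response` over `Kt`.
#' @param R_inf Asymptote; defaults to the attached value.
#' @return One-row tibble `Rmax`, `Kt_max`, `R_inf`, `ratio`, `boundary`.
#' @export
bell_metrics_kt <- function(curve, R_inf = NULL) {
  R_inf <- R_inf %||% attr(curve, "R_inf")
  if (is.null(R_inf) || !is.finite(R_inf)) abort("R_inf unavailable; supply it")
  ok <- is.finite(curve$R)
  v <- curve$value[ok]; R <- curve$R[ok]
  i <- which.max(R)
  boundary <- i == 1 || i == length(v)
  if (boundary) warn("maximum at grid boundary; peak not bracketed")
  pk <- .refine_peak(v, R, i)
  tibble(Rmax = pk$y, Kt_max = pk$x, R_inf = R_inf,
         ratio = pk$y / R_inf, boundary = boundary)
}

#' Bell-shape metrics of an St sweep
#'
#' `R0` is the small-St limit (for the basic variant evaluated analytically
#' at `St = 1e-6 * min(Pt, M1)`); the ratio `RmaxSt / R0 > 1.05` classifies
#' a significant bell.  An interior maximum is required for the bell
#' classification; a curve whose maximum sits on the boundary (monotone
#' rise or decay) is reported with `bell = FALSE`.
#'
#' @param curve A `pdc_dose_response` over `St`.
#' @param R0 Small-St limit; computed if missing.
#' @return One-row tibble `Rmax`, `St_max`, `R0`, `ratio`, `bell`, `boundary`.
#' @export
bell_metrics_st <- function(curve, R0 = NULL) {
  params <- attr(curve, "params")
  if (is.null(R0)) {
    if (!is.null(params) && params$variant == "basic") {
      M1 <- derive_constants(params)$M1
      p0 <- .set_pool(params, "St", 1e-6 * min(params$Pt, M1))
      R0 <- r_from_sk(solve_sk(p0), p0)
    } else {
      R0 <- curve$R[which.min(curve$value)]
    }
  }
  ok <- is.finite(curve$R)
  v <- curve$value[ok]; R <- curve$R[ok]
  i <- which.max(R)
  boundary <- i == 1 || i == length(v)
  pk <- .refine_peak(v, R, i)
  ratio <- pk$y / R0
  tibble(Rmax = pk$y, St_max = pk$x, R0 = R0, ratio = ratio,
         bell = !boundary && ratio > 1.05, boundary = boundary)
}

## 2-D parameter scans --------------------------------------------------------

## Derived axes name a target quantity and the raw rate that realises it.
.apply_axis <- function(params, name, value) {
  switch(name,
    alpha = { params$k2 <- value * params$k1; params },
    St_over_Pt = { params$St <- value * params$Pt; params },
    Pt_over_Kt = { params$Pt <- value * params$Kt; params },
    lambda1_over_lambda2 = { params$lambda1 <- value * params$lambda2; params },
    omega = {
      if (params$kappa1 <= 0) abort("omega axis needs kappa1 > 0")
      params$kappa_m1 <- value * params$kappa1; params
    },
    M3 = {
      if (value <= 0) abort("M3 must be > 0")
      params$lambda3 <- (params$lambda_m3 + params$k3) / value; params
    },
    {
      if (!name %in% c(.pdc_rate_names, .pdc_pool_names)) {
        abort(paste0("unknown axis '", name, "'; raw fields or one of ",
                     "alpha, St_over_Pt, Pt_over_Kt, lambda1_over_lambda2, omega, M3"))
      }
      params[[name]] <- value
      params
    })
}

.scan_metric <- function(params, metric, st_grid_n, kt_grid_n) {
  switch(metric,
    R_inf = sk_inf_kt(params)$R_inf,
    nH = hill_number_analytic(params)$nH,
    bell_st = {
      grid <- 10^seq(log10(params$Kt) - 4, log10(params$Kt) + 4,
                     length.out = st_grid_n)
      cv <- dose_response(params, control = "St", grid = grid, method = "analytic")
      bm <- suppressWarnings(bell_metrics_st(cv))
      ## a maximum on the grid boundary is a monotone curve, not a bell
      if (bm$boundary) 1 else bm$ratio
    },
    bell_kt = {
      grid <- 10^seq(log10(max(params$Pt, 1e-2)) - 2,
                     log10(max(params$Pt, 1e-2)) + 3, length.out = kt_grid_n)
      cv <- dose_response(params, control = "Kt", grid = grid, method = "ode")
      bm <- suppressWarnings(bell_metrics_kt(cv, R_inf = r_inf_extended(params)))
      if (bm$boundary) 1 else bm$ratio
    },
    abort(paste0("unknown metric '", metric, "'")))
}

#' Two-dimensional parameter scan
#'
#' Evaluates a scalar metric of the dose-response over a grid of two varied
#' quantities.  Each axis is either a raw rate/pool field or a derived
#' quantity with a designated free variable: `alpha` (varies `k2`),
#' `St_over_Pt` (varies `St`), `Pt_over_Kt` (varies `Pt`),
#' `lambda1_over_lambda2` (varies `lambda1`), `omega` (varies `kappa_m1`),
#' `M3` (varies `lambda3`).
#'
#' Metrics: `"R_inf"` (large-Kt asymptote), `"nH"` (analytic Hill number),
#' `"bell_st"` (RmaxSt/R0 from an analytic St sweep), `"bell_kt"`
#' (RmaxKt/R_inf from an ODE Kt sweep; phosphatase-active variant).
#'
#' @param params Base `pdc_params` row.
#' @param axis1,axis2 Lists `list(name =, grid =)`.
#' @param metric Metric name.
#' @param threshold Mask threshold; cells with metric > threshold are masked
#'   `TRUE` (default 1.05, the significant-bell criterion).
#' @param st_grid_n,kt_grid_n Sweep resolutions used inside the bell metrics.
#' @return A `pdc_scan` tibble: `axis1`, `axis2`, `value1`, `value2`,
#'   `metric`, `mask`; `NA` metric where the computation failed.
#' @export
scan_2d <- function(params, axis1, axis2, metric = "R_inf", threshold = 1.05,
                    st_grid_n = 200, kt_grid_n = 40) {
  cells <- tidyr::expand_grid(value1 = axis1$grid, value2 = axis2$grid)
  vals <- purrr::pmap_dbl(cells, function(value1, value2) {
    p <- .apply_axis(params, axis1$name, value1)
    p <- .apply_axis(p, axis2$name, value2)
    tryCatch(.scan_metric(p, metric, st_grid_n, kt_grid_n),
             error = function(e) NA_real_)
  })
  out <- tibble(axis1 = axis1$name, axis2 = axis2$name,
                value1 = cells$value1, value2 = cells$value2,
                metric = vals, mask = is.finite(vals) & vals > threshold)
  attr(out, "metric_name") <- metric
  attr(out, "threshold") <- threshold
  attr(out, "params") <- params
  class(out) <- c("pdc_scan", class(out))
  out
}
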