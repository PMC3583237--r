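## Total quasi-steady-state approximation -------------------------------------
##
## For the phosphatase-active extended model the slow variables are
## A = [Sp] + C1 (total phosphorylated substrate outside the PK complex) and
## X = C2 + C4 (total PK), with C1 = [SpP], C2 = [SpPK], C3 = [SK],
## C4 = [PK].  The intermediate complexes are assumed fast and solved
## algebraically at each (A, X); the slow pair then evolves by two ODEs
## whose fixed points give the reduced dose-response.

.tqssa_guard <- function(params) {
  assert_params(params)
  if (params$variant != "complex_P_active") {
    abort(paste0(
      "tQSSA reduction is derived for the phosphatase-active variant ",
      "(slow A-equation has no complex-kinase term); got '", params$variant, "'"))
  }
  dc <- derive_constants(params)
  if (any(is.na(c(dc$M1, dc$M2, dc$M3)))) abort("M1, M2, M3 must be defined for tQSSA")
  c(as.list(dc), as.list(params[c("k1", "k2", "k3", "kappa1", "kappa_m1",
                                  "Kt", "Pt", "St")]))
}

## minus branch of x^2 - b x + c = 0 (continuous with the c -> 0 limit)
.quad_minus <- function(b, c) {
  disc <- pmax(b^2 - 4 * c, 0)
  2 * c / (b + sqrt(disc))   # numerically stable form of (b - sqrt(disc))/2
}

## fast internal path: g is the precomputed guard list, returns numeric
.complexes_fast <- function(A, X, g) {
  C1 <- .quad_minus(A + (g$Pt - X) + g$M1, A * (g$Pt - X))
  C2 <- (A - C1) * X / (g$M3 + A - C1)
  free_sub <- g$St - A - C2
  C3 <- .quad_minus(free_sub + (g$Kt - X) + g$M2, free_sub * (g$Kt - X))
  c(C1 = C1, C2 = C2, C3 = C3)
}

.tqssa_rhs_fast <- function(A, X, g) {
  cx <- .complexes_fast(A, X, g)
  c(dA = -g$k1 * cx[["C1"]] + g$k2 * cx[["C3"]] - g$k3 * cx[["C2"]],
    dX = g$kappa1 * (g$Pt - cx[["C1"]] - X) * (g$Kt - cx[["C3"]] - X) -
      g$kappa_m1 * (X - cx[["C2"]]))
}

#' Fast-complex concentrations at given slow state
#'
#' Solves the quasi-steady-state relations for the intermediate complexes:
#' `M1 C1 = (A - C1)(Pt - C1 - X)` (quadratic in `C1`),
#' `M3 C2 = (A - C1)(X - C2)` (linear in `C2` given `C1`),
#' `M2 C3 = (St - A - C2 - C3)(Kt - C3 - X)` (quadratic in `C3`).
#' The quadratics take the branch continuous with the zero-substrate limit.
#'
#' @param A Total phosphorylated substrate outside the PK complex (uM).
#' @param X Total PK concentration (uM).
#' @param params A phosphatase-active `pdc_params` row.
#' @param Kt Optional override of the total kinase (for sweeps).
#' @return One-row tibble `C1`, `C2`, `C3` with residuals of the three
#'   relations (uM^2) as columns `res1`..`res3`.
#' @export
solve_complexes <- function(A, X, params, Kt = NULL) {
  g <- .tqssa_guard(params)
  if (!is.null(Kt)) g$Kt <- Kt
  if (A < -1e-12 || A > g$St * (1 + 1e-9)) abort("A outside [0, St]")
  if (X < -1e-12 || X > min(g$Pt, g$Kt) + 1e-9) abort("X outside [0, min(Pt, Kt)]")
  cx <- .complexes_fast(A, X, g)
  C1 <- cx[["C1"]]; C2 <- cx[["C2"]]; C3 <- cx[["C3"]]
  tibble(
    C1 = C1, C2 = C2, C3 = C3,
    res1 = g$M1 * C1 - (A - C1) * (g$Pt - C1 - X),
    res2 = g$M3 * C2 - (A - C1) * (X - C2),
    res3 = g$M2 * C3 - (g$St - A - C2 - C3) * (g$Kt - C3 - X))
}

#' Slow-variable derivatives of the tQSSA reduction
#'
#' `dX/dt = kappa1 (Pt - C1 - X)(Kt - C3 - X) - kappa_m1 (X - C2)` and
#' `dA/dt = -k1 C1 + k2 C3 - k3 C2`, with the complexes from
#' [solve_complexes()].
#'
#' @inheritParams solve_complexes
#' @return Named numeric `c(dA, dX)` (uM/s).
#' @export
tqssa_rhs <- function(A, X, params, Kt = NULL) {
  g <- .tqssa_guard(params)
  if (!is.null(Kt)) g$Kt <- Kt
  .tqssa_rhs_fast(A, X, g)
}

.tqssa_fixed_point <- function(params, Kt, start = c(0, 0), g = NULL) {
  g <- g %||% .tqssa_guard(params)
  g$Kt <- Kt
  clamp <- function(ax) c(min(max(ax[1], 0), g$St),
                          min(max(ax[2], 0), min(g$Pt, Kt)))
  f <- function(ax) unname(.tqssa_rhs_fast(ax[1], ax[2], g))
  ## relax the slow ODEs, then polish by damped Newton
  ode_f <- function(t, y, parms) list(f(clamp(y)))
  y <- clamp(start)
  t_end <- 10
  for (i in 1:8) {
    out <- suppressWarnings(
      deSolve::ode(y = y, times = c(0, t_end), func = ode_f, parms = NULL,
                   method = "lsoda", rtol = 1e-10, atol = 1e-12,
                   maxsteps = 50000))
    y <- clamp(as.numeric(out[nrow(out), -1]))
    r <- f(y)
    if (max(abs(r)) < 1e-8) break
    t_end <- t_end * 10
  }
  x <- y; fx <- f(x)
  for (it in 1:60) {
    if (max(abs(fx)) < 1e-12) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7 * max(abs(x[j]), 1e-6)
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (f(clamp(xp)) - fx) / h
    }
    st <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(st)) break
    lam <- 1; ok <- FALSE
    while (lam >= 1e-4) {
      xn <- clamp(x + lam * st)
      fn <- f(xn)
      if (all(is.finite(fn)) && (max(abs(fn)) < max(abs(fx)) || max(abs(fn)) < 1e-12)) {
        ok <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!ok) break
    x <- xn; fx <- fn
  }
  list(A = x[1], X = x[2], residual = max(abs(fx)))
}

#' Reduced-model steady-state dose-response
#'
#' Solves `dA/dt = dX/dt = 0` jointly with the fast-complex relations for
#' each total kinase in `Kt`, continuing the solution along the sweep.  The
#' reported response is the total phosphorylated fraction
#' `R = (A + C2)/St`.
#'
#' @param params A phosphatase-active `pdc_params` row.
#' @param Kt Numeric vector of total kinase values (uM).
#' @return Tibble `Kt`, `A`, `X`, `C1`..`C3`, `R`, `residual`.
#' @export
tqssa_steady_state <- function(params, Kt) {
  g <- .tqssa_guard(params)
  start <- c(0, 0)
  rows <- purrr::map(sort(Kt), function(k) {
    fp <- .tqssa_fixed_point(params, k, start = start, g = g)
    start <<- c(fp$A, fp$X)
    gk <- g; gk$Kt <- k
    cx <- .complexes_fast(fp$A, fp$X, gk)
    tibble(Kt = k, A = fp$A, X = fp$X,
           C1 = cx[["C1"]], C2 = cx[["C2"]], C3 = cx[["C3"]],
           R = (fp$A + cx[["C2"]]) / g$St, residual = fp$residual)
  })
  dplyr::bind_rows(rows)
}
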