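## Mass-action kinetics -------------------------------------------------------
##
## The basic cycle is integrated over six species (S, Sp, SpP, SK, P, K) and
## the extended model over nine (adding PK, SpPK, SPK).  All species are
## carried explicitly so the conservation sums are an independent check on
## the integration rather than an input to it.

.species_basic <- c("S", "Sp", "SpP", "SK", "P", "K")
.species_extended <- c(.species_basic, "PK", "SpPK", "SPK")

#' Species carried by a model variant
#' @param params A `pdc_params` row.
#' @return Character vector of species names (uM).
#' @export
pdc_species <- function(params) {
  if (params$variant == "basic") .species_basic else .species_extended
}

#' Default initial condition
#'
#' All substrate unphosphorylated and free, all enzyme free: `S = St`,
#' `P = Pt`, `K = Kt`, every complex and `Sp` zero.  Dose-response steady
#' states do not depend on this choice (checked by the multistability probe
#' in [steady_state()]); it matters only for transients.
#'
#' @param params A `pdc_params` row.
#' @return Named numeric state vector.
#' @export
pdc_state <- function(params) {
  y <- setNames(numeric(length(pdc_species(params))), pdc_species(params))
  y["S"] <- params$St; y["P"] <- params$Pt; y["K"] <- params$Kt
  y
}

#' Kinetic right-hand sides
#'
#' Time derivatives (uM/s) of every species under mass action.
#' `rhs_basic()` covers the basic cycle (two reaction arms);
#' `rhs_extended()` adds complex formation `P + K <-> PK` and the two
#' complex arms.  The sums of the substrate, kinase and phosphatase species
#' derivatives vanish identically (conservation), and `rhs_extended()`
#' reduces to `rhs_basic()` on the shared species when every complex rate is
#' zero.
#'
#' @param state Named state vector (see [pdc_state()]).
#' @param params A `pdc_params` row.
#' @param recruit Source term (uM/s) on free kinase; used by the
#'   recruitment scenario, 0 otherwise.
#' @return Named vector of derivatives.
#' @export
rhs_basic <- function(state, params) {
  p <- params
  v1f <- p$lambda1 * state[["Sp"]] * state[["P"]]
  v1b <- p$lambda_m1 * state[["SpP"]]
  c1  <- p$k1 * state[["SpP"]]
  v2f <- p$lambda2 * state[["S"]] * state[["K"]]
  v2b <- p$lambda_m2 * state[["SK"]]
  c2  <- p$k2 * state[["SK"]]
  c(S   = -v2f + v2b + c1,
    Sp  = -v1f + v1b + c2,
    SpP =  v1f - v1b - c1,
    SK  =  v2f - v2b - c2,
    P   = -v1f + v1b + c1,
    K   = -v2f + v2b + c2)
}

#' @rdname rhs_basic
#' @export
rhs_extended <- function(state, params, recruit = 0) {
  p <- params
  v1f <- p$lambda1 * state[["Sp"]] * state[["P"]]
  v1b <- p$lambda_m1 * state[["SpP"]]
  c1  <- p$k1 * state[["SpP"]]
  v2f <- p$lambda2 * state[["S"]] * state[["K"]]
  v2b <- p$lambda_m2 * state[["SK"]]
  c2  <- p$k2 * state[["SK"]]
  v3f <- p$lambda3 * state[["Sp"]] * state[["PK"]]
  v3b <- p$lambda_m3 * state[["SpPK"]]
  c3  <- p$k3 * state[["SpPK"]]
  v4f <- p$lambda4 * state[["S"]] * state[["PK"]]
  v4b <- p$lambda_m4 * state[["SPK"]]
  c4  <- p$k4 * state[["SPK"]]
  vkf <- p$kappa1 * state[["P"]] * state[["K"]]
  vkb <- p$kappa_m1 * state[["PK"]]
  c(S    = -v2f + v2b + c1 - v4f + v4b + c3,
    Sp   = -v1f + v1b + c2 - v3f + v3b + c4,
    SpP  =  v1f - v1b - c1,
    SK   =  v2f - v2b - c2,
    P    = -v1f + v1b + c1 - vkf + vkb,
    K    = -v2f + v2b + c2 - vkf + vkb + recruit,
    PK   =  vkf - vkb - v3f + v3b + c3 - v4f + v4b + c4,
    SpPK =  v3f - v3b - c3,
    SPK  =  v4f - v4b - c4)
}

.pdc_rhs <- function(state, params, recruit = 0) {
  if (params$variant == "basic") rhs_basic(state, params)
  else rhs_extended(state, params, recruit)
}

.desolve_func <- function(params, recruit = 0) {
  if (params$variant == "basic") {
    function(t, y, parms) list(unname(rhs_basic(y, params)))
  } else {
    function(t, y, parms) list(unname(rhs_extended(y, params, recruit)))
  }
}

#' Fraction of phosphorylated substrate
#'
#' `R = ([Sp] + [SpP]) / St` for the basic cycle and
#' `R = ([Sp] + [SpP] + [SpPK]) / St` for the extended model.
#'
#' @param state Named state vector, or a trajectory tibble.
#' @param params A `pdc_params` row.
#' @return Numeric in `[0, 1]`.
#' @export
phospho_fraction <- function(state, params) {
  sp <- if (is.data.frame(state)) state$Sp + state$SpP else state[["Sp"]] + state[["SpP"]]
  if (params$variant != "basic") {
    sp <- sp + (if (is.data.frame(state)) state$SpPK else state[["SpPK"]])
  }
  sp / params$St
}

conservation_error <- function(traj, params, recruit = 0) {
  subs <- traj$S + traj$Sp + traj$SpP + traj$SK
  phos <- traj$P + traj$SpP
  kin <- traj$K + traj$SK
  if (params$variant != "basic") {
    ## every ternary complex holds one substrate, one P and one K
    subs <- subs + traj$SpPK + traj$SPK
    phos <- phos + traj$SpPK + traj$PK + traj$SPK
    kin <- kin + traj$SPK + traj$PK + traj$SpPK
  }
  Kt_t <- params$Kt + recruit * traj$time
  rel <- function(x, ref) max(abs(x - ref)) / max(ref, 1e-12)
  c(St = rel(subs, params$St), Pt = rel(phos, params$Pt),
    Kt = max(abs(kin - Kt_t)) / max(max(Kt_t), 1e-12))
}

#' Integrate the kinetic equations
#'
#' Stiff-capable integration (deSolve `lsoda`) of the basic or extended
#' system.  Conservation of the three pools is verified after the run
#' (relative tolerance 1e-8) and tiny negative concentrations from roundoff
#' are clipped to zero in the returned table.
#'
#' @param params A `pdc_params` row.
#' @param times Numeric vector of output times (s), or a single end time.
#' @param y0 Initial state; defaults to [pdc_state()].
#' @param recruit Constant source (uM/s) on free kinase.
#' @param rtol,atol Solver tolerances.
#' @return A `pdc_trajectory` tibble: `time`, one column per species, `R`.
#' @examples
#' tr <- pdc_integrate(pdc_fixture("fig3b"), times = seq(0, 20, 0.5))
#' tail(tr)
#' @export
pdc_integrate <- function(params, times, y0 = NULL, recruit = 0,
                          rtol = 1e-10, atol = 1e-12) {
  assert_params(params)
  if (length(times) == 1) times <- c(0, times)
  y0 <- y0 %||% pdc_state(params)
  if (length(times) == 2 && times[1] == times[2]) {
    out <- rbind(c(times[1], y0))
    colnames(out) <- c("time", names(y0))
  } else {
    out <- deSolve::ode(y = y0, times = times, func = .desolve_func(params, recruit),
                        parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      abort(sprintf("ODE integration failed; last accepted time %.6g s",
                    max(out[, "time"], na.rm = TRUE)))
    }
  }
  traj <- as_tibble(as.data.frame(unclass(out)))
  names(traj)[1] <- "time"
  cons <- conservation_error(traj, params, recruit)
  if (any(cons > 1e-7)) {
    warn(sprintf("conservation drift up to %.2e (relative); tighten tolerances",
                 max(cons)))
  }
  neg <- vapply(traj[-1], min, numeric(1))
  if (min(neg) < -1e-8) {
    warn(sprintf("negative concentration %.2e uM reached; clipped", min(neg)))
  }
  traj[-1] <- lapply(traj[-1], pmax, 0)
  traj$R <- phospho_fraction(traj, params)
  attr(traj, "conservation") <- cons
  attr(traj, "params") <- params
  attr(traj, "recruit") <- recruit
  class(traj) <- c("pdc_trajectory", class(traj))
  traj
}

## Largest gross one-way reaction flux (uM/s) at a state: sets the floor
## below which an RHS residual is indistinguishable from roundoff.
.flux_scale <- function(state, params) {
  s <- function(nm) if (nm %in% names(state)) state[[nm]] else 0
  max(params$lambda1 * s("Sp") * s("P"), params$lambda_m1 * s("SpP"),
      params$k1 * s("SpP"),
      params$lambda2 * s("S") * s("K"), params$lambda_m2 * s("SK"),
      params$k2 * s("SK"),
      params$lambda3 * s("Sp") * s("PK"), params$lambda_m3 * s("SpPK"),
      params$k3 * s("SpPK"),
      params$lambda4 * s("S") * s("PK"), params$lambda_m4 * s("SPK"),
      params$k4 * s("SPK"),
      params$kappa1 * s("P") * s("K"), params$kappa_m1 * s("PK"), 1)
}

## Newton polish of a steady state in conservation-reduced coordinates.
.newton_polish <- function(params, y, max_iter = 50) {
  basic <- params$variant == "basic"
  un <- c("Sp", "SpP", "SK")
  if (!basic) {
    ## only species with live reactions are unknowns; an arm whose rates are
    ## all zero would contribute a zero row/column and a singular Jacobian
    if (params$kappa1 + params$kappa_m1 > 0) un <- c(un, "PK")
    if (params$lambda3 + params$lambda_m3 + params$k3 > 0) un <- c(un, "SpPK")
    if (params$lambda4 + params$lambda_m4 + params$k4 > 0) un <- c(un, "SPK")
  }
  frozen <- setdiff(pdc_species(params), c("S", "P", "K", un))
  full_state <- function(x) {
    x <- setNames(x, un)
    g <- function(nm) if (nm %in% un) x[[nm]] else y[[nm]]
    if (basic) {
      s <- c(S = params$St - g("Sp") - g("SpP") - g("SK"),
             Sp = g("Sp"), SpP = g("SpP"), SK = g("SK"),
             P = params$Pt - g("SpP"), K = params$Kt - g("SK"))
    } else {
      s <- c(S = params$St - g("Sp") - g("SpP") - g("SK") - g("SpPK") - g("SPK"),
             Sp = g("Sp"), SpP = g("SpP"), SK = g("SK"),
             P = params$Pt - g("SpP") - g("SpPK") - g("PK") - g("SPK"),
             K = params$Kt - g("SK") - g("SPK") - g("PK") - g("SpPK"),
             PK = g("PK"), SpPK = g("SpPK"), SPK = g("SPK"))
    }
    s[pdc_species(params)]
  }
  scale_c <- max(params$St, params$Pt, params$Kt, 1)
  resid <- function(x) unname(.pdc_rhs(full_state(x), params)[un])
  x <- unname(y[un])
  f <- resid(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < 1e-13 * max(1, max(abs(x)))) break
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(abs(x[j]), 1e-6)
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (resid(xp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- tryCatch(resid(xn), error = function(e) NULL)
      ok <- !is.null(fn) && all(is.finite(fn)) &&
        (max(abs(fn)) < max(abs(f)) || max(abs(fn)) < 1e-12)
      if (ok || lam < 1e-4) break
      lam <- lam / 2
    }
    if (!ok) break
    x <- xn; f <- fn
  }
  s <- full_state(x)
  list(state = s, residual = max(abs(.pdc_rhs(s, params))),
       flux_scale = .flux_scale(s, params),
       feasible = all(s > -1e-8 * scale_c))
}

#' Numeric steady state by relaxation with Newton polish
#'
#' Relaxes the kinetic equations over exponentially growing time horizons
#' and, once near equilibrium, polishes the fixed point by damped Newton
#' iteration in conservation-reduced coordinates.  The returned state
#' satisfies `max |dy/dt| < 1e-10` uM/s.  With `probe_multistability = TRUE`
#' the relaxation is repeated from random feasible initial conditions and a
#' warning is raised if distinct fixed points are found.
#'
#' @param params A `pdc_params` row.
#' @param y0 Initial state for the relaxation (default [pdc_state()]).
#' @param residual_tol Max-norm residual contract (uM/s).
#' @param t_max Relaxation horizon cap (s).
#' @param probe_multistability Integer; number of extra random starts (0 = off).
#' @return A `pdc_steady_state` one-row tibble: species, `R`, `residual`,
#'   `converged`.
#' @examples
#' ss <- steady_state(pdc_fixture("fig3b"))
#' ss$R
#' @export
steady_state <- function(params, y0 = NULL, residual_tol = 1e-10,
                         t_max = 1e9, probe_multistability = 0) {
  assert_params(params)
  y <- y0 %||% pdc_state(params)
  rate_scale <- max(unlist(params[.pdc_rate_names]), 0.01)
  pool_scale <- max(params$St, params$Pt, params$Kt, 1)
  t_relax <- 1 / rate_scale
  ## Newton alone often converges from a good starting guess (continuation
  ## along a sweep); relaxation is the globaliser when it does not.
  ## the residual target cannot beat roundoff: each RHS component is a sum of
  ## gross fluxes whose factors are reconstructed from conservation, so the
  ## attainable residual is bounded below by machine epsilon times the
  ## largest pool-bounded one-way flux (with headroom)
  ceiling_flux <- max(
    params$lambda1 * params$St * params$Pt, params$lambda2 * params$St * params$Kt,
    params$lambda3 * params$St * params$Pt, params$lambda4 * params$St * params$Pt,
    params$kappa1 * params$Pt * params$Kt,
    (params$lambda_m1 + params$k1 + params$lambda_m2 + params$k2 +
       params$lambda_m3 + params$k3 + params$lambda_m4 + params$k4) * params$St,
    params$kappa_m1 * min(params$Pt, params$Kt), 1)
  target <- function(pol) max(residual_tol, 1e-13 * ceiling_flux)
  best <- .newton_polish(params, y)
  if (!(best$feasible && best$residual < target(best))) {
    repeat {
      out <- deSolve::ode(y = y, times = c(0, t_relax), func = .desolve_func(params),
                          parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-12 * pool_scale)
      y <- setNames(as.numeric(out[nrow(out), -1]), names(y))
      pol <- .newton_polish(params, y)
      if (pol$feasible && pol$residual < target(pol)) { best <- pol; break }
      if (!best$feasible || (pol$feasible && pol$residual < best$residual)) best <- pol
      t_relax <- t_relax * 10
      if (t_relax > t_max) break
    }
  }
  converged <- best$feasible && best$residual < target(best)
  if (!converged) {
    abort(sprintf(
      "steady state did not converge: residual %.3e uM/s after relaxation to %.1e s",
      best$residual, t_relax))
  }
  s <- pmax(best$state, 0)
  if (probe_multistability > 0) {
    ref <- s
    for (i in seq_len(probe_multistability)) {
      yr <- .random_feasible_state(params, i)
      alt <- tryCatch(
        steady_state(params, y0 = yr, residual_tol = residual_tol, t_max = t_max),
        error = function(e) NULL)
      if (!is.null(alt)) {
        da <- max(abs(unlist(alt[1, names(ref)]) - ref)) / max(params$St, params$Pt, params$Kt, 1e-12)
        if (da > 1e-4) warn(sprintf("possible multistability: alternative fixed point found (start %d)", i))
      }
    }
  }
  out <- as_tibble(as.list(s))
  out$R <- phospho_fraction(s, params)
  out$residual <- best$residual
  out$converged <- converged
  attr(out, "params") <- params
  class(out) <- c("pdc_steady_state", class(out))
  out
}

## A random state satisfying the conservation laws (used by the
## multistability probe): distribute each pool over its species.
.random_feasible_state <- function(params, seed) {
  set.seed(seed)
  sp <- pdc_species(params)
  y <- setNames(numeric(length(sp)), sp)
  basic <- params$variant == "basic"
  ## split substrate
  subs <- if (basic) c("S", "Sp") else c("S", "Sp")
  w <- runif(length(subs)); w <- w / sum(w)
  y[subs] <- params$St * w
  ## leave enzymes free (complexes would also consume substrate; keeping the
  ## random split on free species is enough to vary the basin of attraction)
  y["P"] <- params$Pt; y["K"] <- params$Kt
  y
}

#' Transient time to steady state
#'
#' Smallest time after which `|R(t) - R_ss|` stays below `tol` for all later
#' sampled times (the default `tol = 1e-4` is stable in the sense that
#' halving it changes the result only modestly).
#'
#' @param params A `pdc_params` row.
#' @param tol Absolute tolerance on `R`.
#' @param y0 Initial condition (default [pdc_state()]).
#' @param n_grid Number of trajectory samples.
#' @return Transient time (s).
#' @export
transient_time <- function(params, tol = 1e-4, y0 = NULL, n_grid = 4000) {
  ss <- steady_state(params, y0 = NULL)
  y0 <- y0 %||% pdc_state(params)
  r0 <- phospho_fraction(y0, params)
  if (abs(r0 - ss$R) < tol) {
    ## start already within tolerance; confirm it stays there over a short window
    tw <- pdc_integrate(params, times = seq(0, 10, length.out = 50), y0 = y0)
    if (all(abs(tw$R - ss$R) < tol)) return(0)
  }
  t_end <- 10
  repeat {
    traj <- pdc_integrate(params, times = seq(0, t_end, length.out = n_grid), y0 = y0)
    dev <- abs(traj$R - ss$R)
    if (tail(dev, 1) < tol / 10 && any(dev >= tol)) break
    if (all(dev < tol)) break
    t_end <- t_end * 10
    if (t_end > 1e9) abort("R(t) did not settle within the time budget")
  }
  bad <- which(dev >= tol)
  if (!length(bad)) return(0)
  i <- max(bad)
  ## linear refinement across the last crossing
  t1 <- traj$time[i]; t2 <- traj$time[min(i + 1, nrow(traj))]
  d1 <- dev[i]; d2 <- dev[min(i + 1, nrow(traj))]
  if (d1 == d2) return(t2)
  t1 + (d1 - tol) / (d1 - d2) * (t2 - t1)
}

#' @export
print.pdc_steady_state <- function(x, ...) {
  cat(sprintf("<pdc_steady_state: R = %.6g, residual = %.2e uM/s>\n",
              x$R, x$residual))
  NextMethod()
}
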