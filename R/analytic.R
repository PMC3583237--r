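## Exact steady state of the basic cycle --------------------------------------
##
## At steady state the kinase-substrate complex [SK] solves a cubic whose
## coefficients are algebraic in the Michaelis constants, the catalytic
## ratio alpha = k2/k1 and the pools.  The cubic is derived by eliminating
## every other species through the equilibrium relations M1[SpP] = [Sp][P],
## M2[SK] = [S][K], the flux balance [SpP] = alpha [SK] and the three
## conservation laws.  Everything downstream (asymptotes, Hill numbers,
## bell-shape metrics for the basic model) is exact arithmetic on this root.

.analytic_guard <- function(params) {
  assert_params(params)
  if (params$variant != "basic") {
    abort("analytic steady-state machinery applies to the basic variant only")
  }
  if (params$k1 <= 0) abort("alpha = k2/k1 undefined: k1 must be > 0")
  if (params$lambda1 <= 0 || params$lambda2 <= 0) {
    abort("lambda1 and lambda2 must be > 0 for the analytic solution")
  }
  dc <- derive_constants(params)
  list(alpha = dc$alpha, M1 = dc$M1, M2 = dc$M2,
       Kt = params$Kt, Pt = params$Pt, St = params$St)
}

#' Coefficients of the steady-state cubic in [SK]
#'
#' The steady-state `[SK]` of the basic cycle solves
#' `x^3 + Q1 x^2 + Q2 x + Q3 = 0` with `Q1 = -Kt + v1`, `Q2 = u1 Kt + v2`,
#' `Q3 = u2 Kt`, where
#' `u1 = Pt/alpha + (M1 + St)/(alpha + 1)`,
#' `u2 = -Pt St / (alpha (alpha + 1))`,
#' `v1 = -Pt/alpha - (M1 + M2 + St)/(alpha + 1)`,
#' `v2 = Pt (M2 + St) / (alpha (alpha + 1))`.
#'
#' @param params A basic-variant `pdc_params` row.
#' @return One-row tibble `u1`, `u2`, `v1`, `v2`, `Q1`, `Q2`, `Q3`.
#' @export
cubic_coefficients <- function(params) {
  g <- .analytic_guard(params)
  with(g, {
    u1 <- Pt / alpha + (M1 + St) / (alpha + 1)
    u2 <- -Pt * St / (alpha * (alpha + 1))
    v1 <- -Pt / alpha - (M1 + M2 + St) / (alpha + 1)
    v2 <- Pt * (M2 + St) / (alpha * (alpha + 1))
    tibble(u1 = u1, u2 = u2, v1 = v1, v2 = v2,
           Q1 = -Kt + v1, Q2 = u1 * Kt + v2, Q3 = u2 * Kt)
  })
}

#' Steady-state kinase-substrate complex of the basic cycle
#'
#' Solves the cubic of [cubic_coefficients()] and returns the unique
#' physically admissible root: `0 <= [SK] <= min(Kt, St)` and
#' `alpha [SK] < Pt`.  Roots come from the polynomial companion method
#' (`polyroot`) and are polished by one bracketed `uniroot` refinement.
#'
#' @param params A basic-variant `pdc_params` row.
#' @return `[SK]` at steady state (uM).
#' @export
solve_sk <- function(params) {
  g <- .analytic_guard(params)
  cc <- cubic_coefficients(params)
  if (g$Kt == 0 || g$St == 0) return(0)
  cub <- function(x) ((x + cc$Q1) * x + cc$Q2) * x + cc$Q3
  r <- polyroot(c(cc$Q3, cc$Q2, cc$Q1, 1))
  re <- Re(r)[abs(Im(r)) < 1e-7 * pmax(1, Mod(r))]
  hi <- min(g$Kt, g$St, g$Pt / g$alpha)
  adm <- re[re > -1e-9 * hi & re < hi * (1 + 1e-9) &
              re <= min(g$Kt, g$St) * (1 + 1e-9)]
  adm <- sort(pmin(pmax(adm, 0), hi))
  if (!length(adm)) {
    abort(paste0("no admissible root of the steady-state cubic; roots: ",
                 paste(format(r, digits = 6), collapse = ", ")))
  }
  if (length(adm) > 1) {
    ## collapse duplicates from roundoff; genuine multiplicity is flagged
    if (diff(range(adm)) > 1e-6 * max(1, hi)) {
      warn("multiple near-admissible roots; taking the smallest cubic residual")
      adm <- adm[which.min(abs(cub(adm)))]
    } else adm <- adm[1]
  }
  x <- adm[1]
  ## bracketed polish
  scale <- max(abs(unlist(cc[c("Q1", "Q2", "Q3")])), 1)
  if (abs(cub(x)) > 1e-12 * scale) {
    h <- max(1e-8 * hi, 1e-12)
    lo <- max(0, x - h); up <- min(hi, x + h)
    while (sign(cub(lo)) == sign(cub(up)) && (lo > 0 || up < hi)) {
      h <- h * 4; lo <- max(0, x - h); up <- min(hi, x + h)
    }
    if (sign(cub(lo)) != sign(cub(up))) {
      x <- uniroot(cub, c(lo, up), tol = 1e-15 * max(1, hi))$root
    }
  }
  x
}

#' Phosphorylated fraction from the steady-state [SK]
#'
#' `R = (alpha [SK] / St) * (M1 / (Pt - alpha [SK]) + 1)`, valid for
#' `alpha [SK] < Pt`.
#'
#' @param sk Steady-state `[SK]` (uM).
#' @param params A basic-variant `pdc_params` row.
#' @return `R` in `[0, 1]`.
#' @export
r_from_sk <- function(sk, params) {
  g <- .analytic_guard(params)
  if (g$St <= 0) abort("St must be > 0")
  if (any(g$alpha * sk >= g$Pt)) abort("alpha*[SK] must be < Pt")
  g$alpha * sk / g$St * (g$M1 / (g$Pt - g$alpha * sk) + 1)
}

#' Inverse of [r_from_sk()]
#'
#' `[SK] = (b - sqrt(b^2 - 4 R St Pt)) / (2 alpha)` with
#' `b = M1 + Pt + R St`; the minus branch is the one compatible with
#' `alpha [SK] < Pt`.
#'
#' @param R Phosphorylated fraction, `0 <= R <= R_inf`.
#' @inheritParams r_from_sk
#' @return `[SK]` (uM).
#' @export
sk_from_r <- function(R, params) {
  g <- .analytic_guard(params)
  b <- g$M1 + g$Pt + R * g$St
  disc <- b^2 - 4 * R * g$St * g$Pt
  if (any(disc < 0)) abort("discriminant < 0: R not attainable for these parameters")
  ## cancellation-free minus branch
  2 * R * g$St * g$Pt / (g$alpha * (b + sqrt(disc)))
}

#' Total kinase that produces a given steady-state [SK]
#'
#' Inverts the steady-state cubic, which is linear in `Kt`:
#' `Kt = (x^3 + v1 x^2 + v2 x) / (x^2 - u1 x - u2)`.
#'
#' @param sk Steady-state `[SK]` (uM), below the large-Kt asymptote.
#' @inheritParams r_from_sk
#' @return `Kt` (uM).
#' @export
kt_from_sk <- function(sk, params) {
  cc <- cubic_coefficients(params)
  den <- sk^2 - cc$u1 * sk - cc$u2
  if (any(abs(den) < 1e-12 * max(1, abs(cc$u1) * sk))) {
    abort("denominator ~ 0: [SK] is at the large-Kt asymptote")
  }
  kt <- (sk^3 + cc$v1 * sk^2 + cc$v2 * sk) / den
  if (any(kt < 0)) abort("inverted Kt negative: [SK] not attainable")
  kt
}

#' Large-Kt asymptote of [SK] and R
#'
#' As `Kt` grows the cubic degenerates to the quadratic
#' `x^2 - u1 x - u2 = 0`, whose admissible root is
#' `SK_inf = (u1 - sqrt(u1^2 + 4 u2)) / 2`; `R_inf` follows from
#' [r_from_sk()].  Neither depends on `M2` (kinase-substrate binding drops
#' out at saturating kinase).
#'
#' @param params A basic-variant `pdc_params` row.
#' @return One-row tibble `SK_inf`, `R_inf`, `limit = "Kt"`.
#' @export
sk_inf_kt <- function(params) {
  cc <- cubic_coefficients(params)
  ## -2*u2/(u1 + sqrt(...)) is the cancellation-free form of the minus root
  ## (u2 <= 0), accurate even when u1^2 >> |u2| in the saturation limits
  sk <- -2 * cc$u2 / (cc$u1 + sqrt(cc$u1^2 + 4 * cc$u2))
  tibble(SK_inf = sk, R_inf = r_from_sk(sk, params), limit = "Kt")
}

#' Large-St asymptote of R
#'
#' When the maximum kinase speed exceeds the maximum phosphatase speed
#' (`Pt/alpha < Kt`) the substrate is asymptotically fully phosphorylated
#' (`R_inf = 1`, `[SK] -> Pt/alpha`); in the opposite case `R_inf = 0`
#' (`[SK] -> Kt`).  The boundary `Pt/alpha = Kt` is degenerate (the
#' bell-shaped regime lives just above it) and raises an error.
#'
#' @param params A basic-variant `pdc_params` row.
#' @return One-row tibble `SK_inf`, `R_inf`, `limit = "St"`.
#' @export
r_inf_st <- function(params) {
  g <- .analytic_guard(params)
  thr <- g$Pt / g$alpha
  if (thr == g$Kt) abort("degenerate boundary: Pt/alpha == Kt; large-St limit undefined")
  if (thr < g$Kt) tibble(SK_inf = thr, R_inf = 1, limit = "St")
  else tibble(SK_inf = g$Kt, R_inf = 0, limit = "St")
}

#' Hill number of the basic cycle via the response coefficient
#'
#' The response levels are taken relative to the curve's own large-Kt
#' plateau: `R10 = 0.1 R_inf`, `R90 = 0.9 R_inf` (not relative to 1, which
#' would be wrong under partial asymptotic phosphorylation).  `[SK]` at each
#' level comes from [sk_from_r()], the corresponding total kinase from
#' [kt_from_sk()], and `nH = log(81) / log(Kt90 / Kt10)`.
#'
#' @param params A basic-variant `pdc_params` row.
#' @return A `pdc_hill` one-row tibble: `R_inf`, `R10`, `R90`, `SK10`,
#'   `SK90`, `Kt10`, `Kt90`, `nH`.
#' @examples
#' hill_number_analytic(pdc_fixture("fig5a_basic"))$nH  # ~1
#' @export
hill_number_analytic <- function(params) {
  asy <- sk_inf_kt(params)
  if (asy$R_inf <= 0) abort("R_inf must be > 0 for a Hill number")
  lv <- c(0.1, 0.9) * asy$R_inf
  sk <- sk_from_r(lv, params)
  kt <- kt_from_sk(sk, params)
  out <- tibble(R_inf = asy$R_inf, R10 = lv[1], R90 = lv[2],
                SK10 = sk[1], SK90 = sk[2], Kt10 = kt[1], Kt90 = kt[2],
                nH = log(81) / log(kt[2] / kt[1]))
  attr(out, "params") <- params
  class(out) <- c("pdc_hill", class(out))
  out
}
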