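---
title: "Kinetics of phosphorylation-dephosphorylation cycles with kinase-phosphatase complex formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of phosphorylation-dephosphorylation cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcycle)
```

## The model

A phosphorylation-dephosphorylation cycle (PDC) interconverts a substrate
between its unphosphorylated form $S$ and phosphorylated form $S_p$ through
two antagonistic Michaelis-Menten arms,

$$S_p + P \underset{\lambda_{-1}}{\overset{\lambda_1}{\rightleftharpoons}} S_pP
  \xrightarrow{k_1} S + P, \qquad
  S + K \underset{\lambda_{-2}}{\overset{\lambda_2}{\rightleftharpoons}} SK
  \xrightarrow{k_2} S_p + K,$$

with association rates $\lambda_i$ in $\mu M^{-1} s^{-1}$ and dissociation
($\lambda_{-i}$) and catalytic ($k_i$) rates in $s^{-1}$.  Units are fixed
package-wide to $\mu M$ and seconds; there is no unit-conversion layer.  The
conserved pools are the totals $K_t$, $P_t$, $S_t$, and the response of
interest is the total phosphorylated fraction
$R = ([S_p] + [S_pP])/S_t$.

The extended model adds a physical kinase-phosphatase complex
$P + K \rightleftharpoons PK$ (dissociation constant
$\omega = \kappa_{-1}/\kappa_1$) whose enzymatic activity is a modelling
choice: the complex may act as a phosphatase (rates $\lambda_3$,
$\lambda_{-3}$, $k_3$ on $S_p$), as a kinase ($\lambda_4$, $\lambda_{-4}$,
$k_4$ on $S$), as both, or as neither.  `pdc_params()` encodes this as a
`variant` tag, and `validate_variant()` zeroes the association and catalytic
rates of any arm a variant forbids.  Dissociation rates of a deactivated arm
are retained on purpose: a complex bound through that arm may still unbind,
which matters for the triggered-switch scenario below.  This motif is drawn
from phosphoinositide (PI) regulation on endosomes, where several
antagonistic kinase-phosphatase pairs (e.g. Vps34-type kinases and
myotubularin phosphatases) are known or suspected to associate physically.

Within the extended model each ternary complex ($S_pPK$, $SPK$) holds one
kinase and one phosphatase, so the conserved sums are
$K_t = [K] + [SK] + [SPK] + [PK] + [S_pPK]$ and
$P_t = [P] + [S_pP] + [S_pPK] + [PK] + [SPK]$.  These sums are implied
directly by the mass-action equations (each reaction preserves them term by
term); the package treats them as an *a posteriori* check on every
integration rather than as constraints imposed on the solver.

## Exact steady state of the basic cycle

At steady state the net interconversion flux vanishes, which forces
$[S_pP] = \alpha\,[SK]$ with $\alpha = k_2/k_1$, and eliminating all other
species through the two Michaelis relations and the conservation laws turns
the steady state into a single cubic

$$x^3 + Q_1 x^2 + Q_2 x + Q_3 = 0, \qquad x = [SK],$$

with $Q_1 = -K_t + v_1$, $Q_2 = u_1 K_t + v_2$, $Q_3 = u_2 K_t$ and

$$u_1 = \frac{P_t}{\alpha} + \frac{M_1 + S_t}{\alpha + 1},\quad
  u_2 = -\frac{P_t S_t}{\alpha(\alpha+1)},\quad
  v_1 = -\frac{P_t}{\alpha} - \frac{M_1 + M_2 + S_t}{\alpha+1},\quad
  v_2 = \frac{P_t (M_2 + S_t)}{\alpha(\alpha+1)}.$$

These coefficients were re-derived symbolically from the steady-state
relations and are pinned by a regression test against an independent ODE
relaxation (the numeric steady state annihilates the cubic to roundoff).
Because $v_2$ contains no $K_t$, the cubic is *linear* in $K_t$, which makes
the inverse map $K_t(x) = (x^3 + v_1 x^2 + v_2 x)/(x^2 - u_1 x - u_2)$
explicit — the Hill-number machinery below relies on this.

The physically admissible root satisfies $0 \le x \le \min(K_t, S_t)$ and
$\alpha x < P_t$; on $10^5$-scale random parameter sweeps it is unique.
`solve_sk()` obtains the roots by the polynomial companion method
(`polyroot`) and polishes the admissible one with a bracketed `uniroot`
refinement, rather than evaluating the closed-form (Cardano) expressions,
which cancel catastrophically at the extreme pool ratios ($S_t/P_t$ up to
$10^4$) the bell-shape scans visit.

Two asymptotes organise the analysis:

* **Saturating kinase** ($K_t \to \infty$): the cubic degenerates to
  $x^2 - u_1 x - u_2 = 0$, so
  $SK_\infty = (u_1 - \sqrt{u_1^2 + 4u_2})/2$ and the plateau
  $R_\infty = \frac{\alpha SK_\infty}{S_t}\left(\frac{M_1}{P_t - \alpha
  SK_\infty} + 1\right)$ can sit well below one — *partial asymptotic
  phosphorylation*, caused by phosphatase sequestration of substrate.
  $R_\infty$ is independent of the kinase arm's binding rates ($M_2$ drops
  out of $u_1, u_2$), a property the tests verify to machine precision.
* **Saturating substrate** ($S_t \to \infty$): $R \to 1$ when the maximum
  kinase speed exceeds the maximum phosphatase speed ($P_t/\alpha < K_t$)
  and $R \to 0$ otherwise.  The boundary $P_t/\alpha = K_t$ is degenerate
  and is reported as an explicit error; the bell-shaped $S_t$-responses
  live in a narrow band just above it.

## Hill numbers under partial asymptotic phosphorylation

The classical response coefficient compares the control levels giving 10%
and 90% *of full* response.  When the plateau $R_\infty$ is itself below
one, the levels must be taken relative to the plateau:
$R_{10} = 0.1\,R_\infty$, $R_{90} = 0.9\,R_\infty$, inverted to $[SK]$
analytically and then to $K_t$ through the explicit inverse above, giving

$$n_H = \frac{\log 81}{\log\left(K_t^{90}/K_t^{10}\right)}.$$

`hill_number_analytic()` implements this; `hill_fit()` fits a Hill function
$R = R_{max}\,K_t^n/(K^n + K_t^n)$ to a sweep as an independent cross-check.
The two agree within a few percent on sigmoidal curves but are *not*
identical — a response-coefficient value of 2.06 coexists with a fitted
exponent of 2.14 on the zero-order reference set — so the package exposes
both and the tests assert their mutual consistency.  For extended variants
(no closed form) `hill_number_numeric()` applies the same response
coefficient to an ODE-computed sweep, using the parameter-substituted
asymptote for the phosphatase-active variant (see below) or a saturating
$K_t$ evaluation otherwise.

## Numeric steady states

Extended-model steady states exist only implicitly, so `steady_state()`
relaxes the kinetics over exponentially growing horizons (deSolve `lsoda`,
stiff-capable) and polishes the fixed point by damped Newton iteration in
conservation-reduced coordinates.  Two numerical choices matter:

* **Reduced unknowns.**  Only species with live reactions enter the Newton
  system; an arm whose rates are all zero would contribute an identically
  zero row and a singular Jacobian.  Free $S$, $P$, $K$ are reconstructed
  from the conservation sums.
* **Residual target.**  The contract is a max-norm RHS residual below
  $10^{-10}\,\mu M/s$, floored at $10^{-13}$ times the largest pool-bounded
  one-way flux: each RHS component is a difference of gross fluxes, so at
  e.g. $K_t = 10^6\,\mu M$ with $\kappa_1 P_t K_t \sim 10^7\,\mu M/s$ a
  smaller residual than $\sim 10^{-6}$ is unattainable in double precision.
  Wherever the fluxes are of order one — all shipped parameter sets at
  their reference pools — the strict $10^{-10}$ target binds.

Trajectory tolerances default to `rtol = 1e-10`, `atol = 1e-12` (the
fixture rates span $0.01$ to $500\ s^{-1}$); conservation of the three
pools is checked to $10^{-8}$ relative on every integration.  The default
initial condition is fully unphosphorylated with free enzymes; steady
states are checked for independence of the start by the optional
multistability probe (`probe_multistability`), and no multistability has
surfaced on the shipped sets.  Dose-response sweeps continue the solved
state along the grid, which lets the Newton step converge directly almost
everywhere and keeps a 200-point extended-model sweep under a second.

## tQSSA reduction

For the phosphatase-active variant the package implements a total
quasi-steady-state approximation with two slow variables: the total
phosphorylated substrate outside the complex, $A = [S_p] + [S_pP]$, and the
total complex, $X = [S_pPK] + [PK]$.  The intermediate complexes solve, at
fixed $(A, X)$, one quadratic in $C_1 = [S_pP]$, a linear relation for
$C_2 = [S_pPK]$, and one quadratic in $C_3 = [SK]$ — each quadratic on the
branch continuous with the zero-substrate limit, the standard tQSSA choice.
The slow pair then evolves by

$$\dot X = \kappa_1 (P_t - C_1 - X)(K_t - C_3 - X) - \kappa_{-1}(X - C_2),
\qquad \dot A = -k_1 C_1 + k_2 C_3 - k_3 C_2.$$

The $\dot A$ equation has no complex-kinase term, so the reduction is
specific to the phosphatase-active variant; `tqssa_*()` functions refuse
other variants rather than extrapolating to a system the reduction was not
derived for.  Fixed points are found by relaxing the slow pair and
polishing with a two-dimensional Newton step, continued along the $K_t$
sweep.  A useful structural fact, confirmed by the tests at machine
precision: the *steady states* of the reduced system coincide exactly with
those of the full model (at a true fixed point the fast-complex relations
hold exactly), so the approximation quality of tQSSA shows in transients,
not in the dose-response curves.

## Bell-shaped responses and scans

Bell metrics quantify non-monotonicity: `bell_metrics_kt()` reports
$R_{max}/R_\infty$ over a $K_t$ sweep, and `bell_metrics_st()` reports
$R_{max}/R_0$ over an $S_t$ sweep with $R_0$ evaluated analytically at
$S_t = 10^{-6}\min(P_t, M_1)$ (halving this changes $R_0$ by under
$10^{-4}$).  Peaks are refined by three-point parabolic interpolation in
log-control space; a maximum on the grid boundary is flagged, never
silently refined, and boundary maxima are excluded from the bell
classification (threshold: ratio $> 1.05$).

For the phosphatase-active variant the saturating-$K_t$ plateau follows by
parameter substitution: at large $K_t$ essentially no free phosphatase
remains and the cycle reduces to a basic one whose phosphatase is the
complex, so replacing $(\lambda_1, \lambda_{-1}, k_1)$ by
$(\lambda_3, \lambda_{-3}, k_3)$ in the $R_\infty$ formula gives the limit
(`r_inf_extended()`); the large-$K_t$ ODE steady state confirms it.

`scan_2d()` evaluates these metrics over grids of two varied quantities.
Derived axes follow fixed conventions — `alpha` varies $k_2$, `St_over_Pt`
varies $S_t$, `Pt_over_Kt` varies $P_t$, `lambda1_over_lambda2` varies
$\lambda_1$, `omega` varies $\kappa_{-1}$, `M3` varies $\lambda_3$ — so a
scan axis never silently changes more than one rate.  Where a fixture lists
a base value for a rate that an axis then varies (e.g. $\kappa_{-1}$ under
an `omega` axis), the base value is simply the pre-sweep starting point.

## Transient scenarios

Two mechanisms for the transient PI pulse seen during endosome maturation:

* **Recruitment** (`simulate_recruitment()`): the kinase arrives on the
  membrane at a constant rate, implemented as a source term on *free*
  kinase (newly recruited enzyme arrives unbound), so
  $K_t(t) = K_t(0) + \text{rate}\cdot t$; the shipped `fig9_recruitment`
  set starts from $K_t(0) = 0$ (an initial pool is a parameter away).
  Phosphatase level is fixed and the complex acts as a phosphatase, so the
  pulse is the bell-shaped $K_t$ dose-response traversed in time.
* **Triggered switch** (`simulate_trigger()`): fixed pools; at the switch
  time the complex's activity flips from kinase to phosphatase.  The
  integration restarts exactly at the switch.  Substrate bound through the
  deactivated kinase arm is *not* teleported: by default it drains at the
  retained dissociation rate (`bound = "drain"`), avoiding a discontinuous
  mass redistribution the model itself gives no rule for; an instantaneous
  release (`bound = "release"`) is available behind the flag.

`peak_time()` reports the refined argmax of $R(t)$ and flags a maximum at
the window end as a non-peak.  One empirical caution: with the shipped
`fig9_recruitment` parameters the quasi-static bell of $R(K_t)$ peaks near
$K_t \approx 3.5\,\mu M$, so at the slow recruitment rate of
$3\times10^{-4}\,\mu M/s$ the transient maximum falls around
$1.2\times10^4$ s, with a shallow decay thereafter (the plateau is the
substituted asymptote, about 0.73); the triggered scenario, by
construction, peaks exactly at its 300 s switch.  The transient-time
analysis (`transient_time()`, default tolerance $10^{-4}$ on $|R - R_{ss}|$,
stable to tolerance halving within 20%) shows the extended model's
settling times tracking the basic model's within ten percent across the
$K_t$ sweep, both peaking at the ultrasensitive threshold.

## What the parameter sets emulate — and what they do not

The shipped fixtures (`pdc_fixture_names()`) are printed parameterizations
of the dose-response and scenario analyses; they are exact inputs, not
random data, so every quantitative check in the package is deterministic
apart from the explicitly seeded random-parameter property tests.
`sample_params()` draws log-uniform parameter sets in user-given bounds;
the property suites use moderate, well-conditioned ranges
($\lambda, k \in [0.1, 10]$, pools in $[0.1, 100]\,\mu M$) — wide enough to
exercise saturation and sequestration regimes, while staying clear of the
regime where finite-precision flux cancellation (discussed above) dominates.
Passing tests therefore demonstrate internal consistency of the analytics,
the reduction and the solvers under mass-action assumptions; they say
nothing about stochasticity, spatial effects, enzyme turnover, or the
multi-lipid regulatory network surrounding a real PI cycle, all of which
are out of scope.

## Problem sizes used in the shipped checks

Dose-response grids default to 200 log-spaced points spanning
$[10^{-2}, 10^3]$ times the reference pool; the test and acceptance runs
use 25-400 points per sweep, 100-200 random parameter sets per property,
a 10-point $K_t$ grid for the transient-time comparison, and 2000-4000
trajectory samples for the scenarios — sizes at which every check
reproduces stably (grid-halving changes Hill and bell metrics by well
under 1%).

## Worked example

```{r example, eval = FALSE}
library(pdcycle)

p <- pdc_fixture("fig6a")          # phosphatase-active complex, St >> Pt
curve_ode <- dose_response(p, control = "Kt", method = "ode", n = 60)
bell_metrics_kt(curve_ode)         # Rmax / R_inf > 1: bell-shaped
autoplot(curve_ode)

pb <- p
pb[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
pb$variant <- "basic"
hill_number_analytic(pb)           # response coefficient of the basic cycle
```

## Known limitations

* The analytic machinery covers the basic variant only; extended-model
  steady states are numeric (with the substituted asymptote as the one
  closed-form anchor).
* The tQSSA module is restricted to the phosphatase-active variant, by
  derivation.
* Uniqueness of extended-model steady states is assumed (and probed), not
  proven.
* The residual contract degrades gracefully (flux-scaled floor) at extreme
  pool sizes; reported residuals always state what was achieved.
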