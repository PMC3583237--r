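## Named parameter sets -------------------------------------------------------
##
## Registry of the printed parameterizations used throughout the package's
## examples, tests and figure-level reproductions.  Each entry is the exact
## printed set; where a figure sweeps a control variable (Kt or St), the
## fixture carries a reference value of that pool and the sweep supplies the
## grid.  This registry is the single source of truth for tests.

.fixture_registry <- function() {
  list(
    ## basic-cycle baselines for the asymptote / Hill-number surfaces
    fig3a = list(lambda1 = 1, lambda_m1 = 1, k1 = 1,
                 lambda2 = 1, lambda_m2 = 1, k2 = 0.01,
                 Kt = 1, Pt = 1, St = 10, variant = "basic"),
    fig3b = list(lambda1 = 1, lambda_m1 = 1, k1 = 1,
                 lambda2 = 1, lambda_m2 = 1, k2 = 1,
                 Kt = 10, Pt = 1, St = 100, variant = "basic"),
    ## bell-shaped St-sweeps in the basic model; Pt is a stated fraction of Kt
    fig4a_p1001 = list(lambda1 = 0.1, lambda_m1 = 0.1, k1 = 1,
                       lambda2 = 0.1, lambda_m2 = 0.1, k2 = 0.1,
                       Kt = 2000, Pt = 0.1001 * 2000, St = 1, variant = "basic"),
    fig4a_p2    = list(lambda1 = 0.1, lambda_m1 = 0.1, k1 = 1,
                       lambda2 = 0.1, lambda_m2 = 0.1, k2 = 0.1,
                       Kt = 2000, Pt = 0.2 * 2000, St = 1, variant = "basic"),
    fig4a_p08   = list(lambda1 = 0.1, lambda_m1 = 0.1, k1 = 1,
                       lambda2 = 0.1, lambda_m2 = 0.1, k2 = 0.1,
                       Kt = 2000, Pt = 0.08 * 2000, St = 1, variant = "basic"),
    fig4b       = list(lambda1 = 0.1, lambda_m1 = 0.1, k1 = 1,
                       lambda2 = 0.1, lambda_m2 = 0.1, k2 = 0.1,
                       Kt = 2000, Pt = 0.1001 * 2000, St = 1, variant = "basic"),
    ## ultrasensitivity outside the zero-order regime (St < Pt)
    fig5a_basic   = list(lambda1 = 1, lambda_m1 = 10, k1 = 100,
                         lambda2 = 1, lambda_m2 = 10, k2 = 100,
                         Kt = 1, Pt = 10, St = 1, variant = "basic"),
    fig5a_Kactive = list(lambda1 = 1, lambda_m1 = 10, k1 = 100,
                         lambda2 = 1, lambda_m2 = 10, k2 = 100,
                         lambda4 = 100, lambda_m4 = 10, k4 = 0.01,
                         kappa1 = 1, kappa_m1 = 10,
                         Kt = 1, Pt = 10, St = 1, variant = "complex_K_active"),
    fig5b_basic   = list(lambda1 = 1, lambda_m1 = 10, k1 = 100,
                         lambda2 = 1, lambda_m2 = 10, k2 = 100,
                         Kt = 1, Pt = 10, St = 1, variant = "basic"),
    fig5b_Pactive = list(lambda1 = 1, lambda_m1 = 10, k1 = 100,
                         lambda2 = 1, lambda_m2 = 10, k2 = 100,
                         lambda3 = 100, lambda_m3 = 10, k3 = 0.01,
                         kappa1 = 1, kappa_m1 = 10,
                         Kt = 1, Pt = 10, St = 1, variant = "complex_P_active"),
    ## bell-shaped Kt-sweeps, phosphatase-active complex
    fig6a = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                 lambda2 = 20, lambda_m2 = 10, k2 = 1,
                 lambda3 = 1, lambda_m3 = 10, k3 = 100,
                 kappa1 = 1, kappa_m1 = 50,
                 Kt = 1, Pt = 1, St = 10, variant = "complex_P_active"),
    fig6b = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                 lambda2 = 20, lambda_m2 = 10, k2 = 1,
                 lambda3 = 1, lambda_m3 = 10, k3 = 100,
                 kappa1 = 1, kappa_m1 = 50,
                 Kt = 1, Pt = 1, St = 0.1, variant = "complex_P_active"),
    ## robustness scan base (omega = 10 before the omega axis overwrites it)
    fig7  = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                 lambda2 = 20, lambda_m2 = 10, k2 = 1,
                 lambda3 = 1, lambda_m3 = 10, k3 = 100,
                 kappa1 = 1, kappa_m1 = 10,
                 Kt = 1, Pt = 1, St = 10, variant = "complex_P_active"),
    ## transient-time comparison
    fig8_basic    = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                         lambda2 = 20, lambda_m2 = 10, k2 = 1,
                         Kt = 1, Pt = 1, St = 10, variant = "basic"),
    fig8_extended = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                         lambda2 = 20, lambda_m2 = 10, k2 = 1,
                         lambda3 = 1, lambda_m3 = 10, k3 = 100,
                         kappa1 = 1, kappa_m1 = 50,
                         Kt = 1, Pt = 1, St = 10, variant = "complex_P_active"),
    ## transient phosphoinositide scenarios; fig9_trigger is the pre-switch
    ## (kinase-active complex) set, fig9_recruitment the phosphatase-active
    ## set swept by linear kinase recruitment from Kt = 0
    fig9_trigger = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                        lambda2 = 1, lambda_m2 = 10, k2 = 1,
                        lambda4 = 75, lambda_m4 = 1, k4 = 100,
                        lambda_m3 = 10,
                        kappa1 = 1, kappa_m1 = 50,
                        Kt = 0.1, Pt = 0.2, St = 300, variant = "complex_K_active"),
    fig9_recruitment = list(lambda1 = 1, lambda_m1 = 10, k1 = 1,
                            lambda2 = 1, lambda_m2 = 10, k2 = 1,
                            lambda3 = 10, lambda_m3 = 10, k3 = 500,
                            kappa1 = 1, kappa_m1 = 50,
                            Kt = 0, Pt = 0.2, St = 300, variant = "complex_P_active")
  )
}

#' Shipped parameter sets
#'
#' `pdc_fixture()` returns one of the named parameter sets shipped with the
#' package (named after the dose-response and scenario figures they
#' reproduce); `pdc_fixture_names()` lists them.
#'
#' @param name Fixture identifier, e.g. `"fig6a"`.
#' @return A `pdc_params` row.
#' @examples
#' pdc_fixture("fig6a")
#' pdc_fixture_names()
#' @export
pdc_fixture <- function(name) {
  reg <- .fixture_registry()
  if (!is.character(name) || length(name) != 1 || !name %in% names(reg)) {
    abort(paste0(
      "unknown fixture '", paste(name, collapse = ","), "'; available: ",
      paste(names(reg), collapse = ", ")))
  }
  do.call(pdc_params, reg[[name]])
}

#' @rdname pdc_fixture
#' @export
pdc_fixture_names <- function() names(.fixture_registry())
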