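## Shared helpers for the suite -----------------------------------------------

## moderate, well-conditioned random basic-cycle sets for property checks
random_basic_sets <- function(n, seed = 1L) {
  sample_params(
    ranges = list(lambda1 = c(0.1, 10), lambda_m1 = c(0.1, 10), k1 = c(0.1, 10),
                  lambda2 = c(0.1, 10), lambda_m2 = c(0.1, 10), k2 = c(0.1, 10),
                  Kt = c(0.1, 50), Pt = c(0.1, 50), St = c(0.1, 100)),
    n = n, seed = seed)
}

## extract row i of a stacked pdc_params tibble as a usable params object
params_row <- function(ps, i) {
  p <- ps[i, ]
  class(p) <- unique(c("pdc_params", class(p)))
  p
}

## independent term-by-term expansion of the basic-cycle kinetics, written
## directly from the reaction scheme (binding, unbinding, catalysis) rather
## than via the package's flux bookkeeping
oracle_rhs_basic <- function(y, p) {
  bind1 <- p$lambda1 * y[["Sp"]] * y[["P"]]   # Sp + P -> SpP
  unb1 <- p$lambda_m1 * y[["SpP"]]            # SpP -> Sp + P
  cat1 <- p$k1 * y[["SpP"]]                   # SpP -> S + P
  bind2 <- p$lambda2 * y[["S"]] * y[["K"]]    # S + K -> SK
  unb2 <- p$lambda_m2 * y[["SK"]]             # SK -> S + K
  cat2 <- p$k2 * y[["SK"]]                    # SK -> Sp + K
  c(S = unb2 + cat1 - bind2,
    Sp = unb1 + cat2 - bind1,
    SpP = bind1 - unb1 - cat1,
    SK = bind2 - unb2 - cat2,
    P = unb1 + cat1 - bind1,
    K = unb2 + cat2 - bind2)
}

oracle_rhs_extended <- function(y, p) {
  bind1 <- p$lambda1 * y[["Sp"]] * y[["P"]]
  unb1 <- p$lambda_m1 * y[["SpP"]]
  cat1 <- p$k1 * y[["SpP"]]
  bind2 <- p$lambda2 * y[["S"]] * y[["K"]]
  unb2 <- p$lambda_m2 * y[["SK"]]
  cat2 <- p$k2 * y[["SK"]]
  bind3 <- p$lambda3 * y[["Sp"]] * y[["PK"]]  # Sp + PK -> SpPK
  unb3 <- p$lambda_m3 * y[["SpPK"]]
  cat3 <- p$k3 * y[["SpPK"]]                  # SpPK -> S + PK
  bind4 <- p$lambda4 * y[["S"]] * y[["PK"]]   # S + PK -> SPK
  unb4 <- p$lambda_m4 * y[["SPK"]]
  cat4 <- p$k4 * y[["SPK"]]                   # SPK -> Sp + PK
  bindk <- p$kappa1 * y[["P"]] * y[["K"]]     # P + K -> PK
  unbk <- p$kappa_m1 * y[["PK"]]
  c(S = unb2 + cat1 - bind2 + unb4 + cat3 - bind4,
    Sp = unb1 + cat2 - bind1 + unb3 + cat4 - bind3,
    SpP = bind1 - unb1 - cat1,
    SK = bind2 - unb2 - cat2,
    P = unb1 + cat1 - bind1 + unbk - bindk,
    K = unb2 + cat2 - bind2 + unbk - bindk,
    PK = bindk - unbk + unb3 + cat3 - bind3 + unb4 + cat4 - bind4,
    SpPK = bind3 - unb3 - cat3,
    SPK = bind4 - unb4 - cat4)
}

## random non-negative state respecting rough magnitude of the pools
random_state <- function(params, seed) {
  set.seed(seed)
  sp <- pdc_species(params)
  y <- setNames(runif(length(sp)) * max(params$St, 1) / length(sp), sp)
  y
}
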