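## Frozen reference values below were derived symbolically from the
## steady-state relations and verified against independent ODE relaxation
## (deSolve) before being fixed here.

test_that("cubic coefficients match the symbolic expansion on the reference set", {
  p <- pdc_fixture("fig3b")  # all rates 1, Pt = 1, St = 100, Kt = 10
  cc <- cubic_coefficients(p)
  expect_equal(cc$u1, 52)
  expect_equal(cc$u2, -50)
  expect_equal(cc$v1, -53)
  expect_equal(cc$v2, 51)
  expect_equal(cc$Q1, -63)
  expect_equal(cc$Q2, 571)
  expect_equal(cc$Q3, -500)

  ## structural identities Q1 = -Kt + v1, Q2 = u1 Kt + v2, Q3 = u2 Kt on
  ## random sets, and the numeric ODE steady state annihilates the cubic
  ps <- random_basic_sets(10, seed = 5)
  for (i in seq_len(nrow(ps))) {
    q <- params_row(ps, i)
    cc <- cubic_coefficients(q)
    expect_equal(cc$Q1, -q$Kt + cc$v1)
    expect_equal(cc$Q2, cc$u1 * q$Kt + cc$v2)
    expect_equal(cc$Q3, cc$u2 * q$Kt)
  }
  sk_num <- steady_state(p)$SK
  cc <- cubic_coefficients(p)
  expect_lt(abs(sk_num^3 + cc$Q1 * sk_num^2 + cc$Q2 * sk_num + cc$Q3),
            1e-8 * max(abs(unlist(cc))))
})

test_that("degenerate pools simplify the cubic as the algebra dictates", {
  p <- pdc_fixture("fig3b")
  p0 <- p; p0$St <- 0
  expect_equal(cubic_coefficients(p0)$u2, 0)
  expect_equal(solve_sk(p0), 0)

  pp <- p; pp$Pt <- 0
  cc <- cubic_coefficients(pp)
  dc <- derive_constants(pp)
  expect_equal(cc$u1, (dc$M1 + pp$St) / (dc$alpha + 1))
  expect_equal(cc$u2, 0)

  pk <- p; pk$Kt <- 0
  expect_equal(solve_sk(pk), 0)

  expect_error(cubic_coefficients(pdc_params(lambda1 = 1, lambda2 = 1, k2 = 1,
                                             Kt = 1, Pt = 1, St = 1)), "k1")
})

test_that("the admissible cubic root is unique and matches the ODE steady state", {
  p <- pdc_fixture("fig3b")
  sk <- solve_sk(p)
  expect_equal(sk, steady_state(p)$SK, tolerance = 1e-6)

  ps <- random_basic_sets(100, seed = 17)
  for (i in seq_len(nrow(ps))) {
    q <- params_row(ps, i)
    cc <- cubic_coefficients(q)
    dc <- derive_constants(q)
    ## brute-force enumeration: count admissible roots directly
    r <- polyroot(c(cc$Q3, cc$Q2, cc$Q1, 1))
    re <- Re(r)[abs(Im(r)) < 1e-9 * pmax(1, Mod(r))]
    hi <- min(q$Kt, q$St, q$Pt / dc$alpha)
    n_adm <- sum(re > 1e-9 * hi & re < hi * (1 - 1e-9))
    expect_lte(n_adm, 1)
    sk <- solve_sk(q)
    expect_true(sk >= 0 && sk <= hi)
    expect_lt(abs(sk^3 + cc$Q1 * sk^2 + cc$Q2 * sk + cc$Q3),
              1e-10 * max(abs(unlist(cc[c("Q1", "Q2", "Q3")]))))
  }
})

test_that("R follows from [SK] and never exceeds one", {
  p <- pdc_fixture("fig3b")
  expect_equal(r_from_sk(0, p), 0)
  expect_error(r_from_sk(p$Pt / derive_constants(p)$alpha, p), "Pt")

  ps <- random_basic_sets(1000, seed = 23)
  R <- vapply(seq_len(nrow(ps)), function(i) {
    q <- params_row(ps, i)
    r_from_sk(solve_sk(q), q)
  }, numeric(1))
  expect_true(all(R >= 0 & R <= 1 + 1e-12))
})

test_that("sk_from_r inverts r_from_sk to near machine precision", {
  ps <- random_basic_sets(50, seed = 31)
  for (i in seq_len(nrow(ps))) {
    q <- params_row(ps, i)
    rinf <- sk_inf_kt(q)$R_inf
    for (R in c(0.1, 0.5, 0.9) * rinf) {
      expect_equal(r_from_sk(sk_from_r(R, q), q), R, tolerance = 1e-12)
    }
  }
  ## series limit R -> 0 => [SK] -> 0
  q <- pdc_fixture("fig3b")
  expect_lt(sk_from_r(1e-12, q), 1e-9)
})

test_that("kt_from_sk inverts solve_sk along random admissible sweeps", {
  ps <- random_basic_sets(50, seed = 41)
  for (i in seq_len(nrow(ps))) {
    q <- params_row(ps, i)
    sk <- solve_sk(q)
    if (sk <= 0) next
    kt <- kt_from_sk(sk, q)
    expect_equal(kt, q$Kt, tolerance = 1e-7, label = paste("set", i))
    ## and the full round trip through the cubic
    q2 <- q; q2$Kt <- kt
    expect_equal(solve_sk(q2), sk, tolerance = 1e-9)
  }
  ## at the large-Kt asymptote the denominator vanishes
  q <- pdc_fixture("fig3b")
  expect_error(kt_from_sk(sk_inf_kt(q)$SK_inf, q), "asymptote")
})

test_that("large-Kt asymptote is exact, M2-independent, and matches the ODE limit", {
  p <- pdc_fixture("fig3b")
  asy <- sk_inf_kt(p)
  expect_equal(asy$SK_inf, 0.9800079936, tolerance = 1e-8)  # minus root of x^2-52x+50
  expect_equal(asy$R_inf, 0.9901999201, tolerance = 1e-8)

  ## perturbing the kinase arm's binding rates leaves the asymptote unchanged
  p2 <- p; p2$lambda2 <- 17; p2$lambda_m2 <- 0.3
  expect_equal(sk_inf_kt(p2)$SK_inf, asy$SK_inf, tolerance = 1e-14)

  ## numeric steady state at saturating kinase approaches R_inf
  pbig <- p; pbig$Kt <- 1e6 * p$Pt
  expect_equal(steady_state(pbig)$R, asy$R_inf, tolerance = 1e-4)
})

test_that("asymptote limits follow the saturation analysis", {
  p <- pdc_fixture("fig3b")
  ## St/Pt -> infinity drives R_inf -> 1
  p1 <- p; p1$St <- 1e8 * p$Pt
  expect_equal(sk_inf_kt(p1)$R_inf, 1, tolerance = 1e-3)
  ## alpha -> infinity drives R_inf -> 1
  p2 <- p; p2$k2 <- 1e8 * p$k1
  expect_equal(sk_inf_kt(p2)$R_inf, 1, tolerance = 1e-3)
  ## lambda1 -> infinity: branch depends on Pt/alpha vs St/(alpha+1).
  ## First branch: SK_inf -> Pt/alpha and a perturbation expansion of the
  ## quadratic (M1 -> 0) gives R_inf -> 1 - Pt/(alpha St), verified by
  ## 60-digit arithmetic; the limit approaches 1 only for St >> Pt/alpha.
  p3 <- p; p3$lambda1 <- 1e8          # Pt/alpha = 1 < St/2 = 50
  a3 <- derive_constants(p3)$alpha
  expect_equal(sk_inf_kt(p3)$R_inf, 1 - p3$Pt / (a3 * p3$St), tolerance = 1e-6)
  p3b <- p3; p3b$St <- 1e6 * p3$Pt
  expect_equal(sk_inf_kt(p3b)$R_inf, 1, tolerance = 1e-3)
  ## second branch: SK_inf -> St/(alpha+1), R_inf -> alpha/(alpha+1) exactly
  p4 <- p; p4$St <- 1; p4$Pt <- 10; p4$lambda1 <- 1e8  # Pt/alpha = 10 > 0.5
  alpha <- derive_constants(p4)$alpha
  expect_equal(sk_inf_kt(p4)$R_inf, alpha / (alpha + 1), tolerance = 1e-3)
})

test_that("large-St limit selects the winning enzyme and flags the boundary", {
  mk <- function(Pt, Kt) pdc_params(lambda1 = 1, lambda_m1 = 1, k1 = 1,
                                    lambda2 = 1, lambda_m2 = 1, k2 = 1,
                                    Kt = Kt, Pt = Pt, St = 10)
  expect_equal(r_inf_st(mk(Pt = 1, Kt = 2))$R_inf, 1)   # Pt/alpha < Kt
  expect_equal(r_inf_st(mk(Pt = 4, Kt = 2))$R_inf, 0)   # Pt/alpha > Kt
  expect_error(r_inf_st(mk(Pt = 2, Kt = 2)), "degenerate")
})

test_that("R increases monotonically with Kt in the basic cycle", {
  ps <- random_basic_sets(30, seed = 53)
  for (i in seq_len(nrow(ps))) {
    q <- params_row(ps, i)
    kts <- q$Kt * c(0.5, 1, 2, 5, 10)
    R <- vapply(kts, function(k) { q$Kt <- k; r_from_sk(solve_sk(q), q) }, numeric(1))
    expect_true(all(diff(R) > -1e-12), label = paste("set", i))
  }
})

test_that("response-coefficient Hill numbers reproduce the printed reference values", {
  ## frozen from the analytic pipeline, cross-checked against ODE steady
  ## states at the computed Kt10/Kt90 (R there equals 0.1/0.9 of R_inf)
  h5 <- hill_number_analytic(pdc_fixture("fig5a_basic"))
  expect_equal(h5$nH, 1.0028386, tolerance = 1e-6)
  expect_lt(h5$Kt10, h5$Kt90)
})

test_that("Hill levels sit exactly at 10%/90% of the plateau on the ODE curve", {
  pb <- pdc_fixture("fig6a")
  pb[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
  pb$variant <- "basic"
  h <- hill_number_analytic(pb)
  for (lv in c("Kt10", "Kt90")) {
    p <- pb; p$Kt <- h[[lv]]
    frac <- steady_state(p)$R / h$R_inf
    expect_equal(frac, if (lv == "Kt10") 0.1 else 0.9, tolerance = 1e-5)
  }
})

test_that("response-coefficient nH agrees with a Hill-function fit within 5%", {
  pb <- pdc_fixture("fig6a")
  pb[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
  pb$variant <- "basic"
  h <- hill_number_analytic(pb)
  grid <- 10^seq(log10(h$Kt10) - 2, log10(h$Kt90) + 2, length.out = 400)
  cv <- dose_response(pb, control = "Kt", grid = grid, method = "analytic")
  fit <- hill_fit(cv)
  expect_lt(abs(fit$nH - h$nH) / h$nH, 0.05)
})
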