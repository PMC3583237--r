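test_that("analytic sweeps equal the cubic solution pointwise and match the ODE backend", {
  p <- pdc_fixture("fig5a_basic")
  grid <- 10^seq(-1, 2, length.out = 20)
  cv <- dose_response(p, control = "Kt", grid = grid, method = "analytic")
  ref <- vapply(grid, function(k) { q <- p; q$Kt <- k; r_from_sk(solve_sk(q), q) },
                numeric(1))
  expect_equal(cv$R, ref)

  co <- dose_response(p, control = "Kt", grid = grid, method = "ode")
  expect_lt(max(abs(co$R - cv$R)), 1e-6)
})

test_that("sweep guards reject unusable configurations", {
  expect_error(dose_response(pdc_fixture("fig6a"), method = "analytic"), "basic")
  expect_error(dose_response(pdc_fixture("fig6a"), control = "St", method = "tqssa"), "Kt")
  expect_error(dose_response(pdc_fixture("fig3b"), grid = c(-1, 1)), "positive")
})

test_that("P-active ultrasensitive rise happens where kinase overtakes total phosphatase", {
  p <- pdc_fixture("fig5b_Pactive")
  grid <- 10^seq(-1.5, 2.5, length.out = 35)
  cv <- dose_response(p, control = "Kt", grid = grid, method = "ode")
  ## sigmoidal rise between Kt ~ Pt/50 and Kt ~ Pt: low below, high above
  expect_lt(max(cv$R[cv$value < 0.02 * p$Pt]), 0.05)
  expect_gt(min(cv$R[cv$value > 10 * p$Pt]), 0.9)
  expect_true(all(diff(cv$R) > -1e-8))
})

test_that("substituted asymptote matches identity and the large-Kt ODE limit", {
  ## complex arm identical to the phosphatase arm => same asymptote as basic
  p <- pdc_fixture("fig6a")
  p$lambda3 <- p$lambda1; p$lambda_m3 <- p$lambda_m1; p$k3 <- p$k1
  pb <- p; pb[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
  pb$variant <- "basic"
  expect_equal(r_inf_extended(p), sk_inf_kt(pb)$R_inf, tolerance = 1e-12)

  ## fig6a: the large-Kt ODE steady state approaches the substituted limit
  p6 <- pdc_fixture("fig6a")
  rinf <- r_inf_extended(p6)
  pbig <- p6; pbig$Kt <- 1e5 * p6$Pt
  expect_equal(steady_state(pbig)$R, rinf, tolerance = 1e-3)

  ## a stronger complex phosphatase lowers the asymptote
  rk <- vapply(c(50, 100, 200, 400), function(k3) {
    q <- p6; q$k3 <- k3; r_inf_extended(q)
  }, numeric(1))
  expect_true(all(diff(rk) < 0))
})

test_that("numeric Hill numbers agree with the analytic response coefficient", {
  p <- pdc_fixture("fig5a_basic")
  h <- hill_number_analytic(p)
  grid <- 10^seq(log10(h$Kt10) - 1.5, log10(h$Kt90) + 1.5, length.out = 150)
  cv <- dose_response(p, control = "Kt", grid = grid, method = "analytic")
  hn <- hill_number_numeric(cv, R_inf = h$R_inf)
  expect_lt(abs(hn$nH - h$nH) / h$nH, 0.01)
})

test_that("non-monotone curves are routed to bell metrics, not Hill numbers", {
  p <- pdc_fixture("fig6a")
  grid <- 10^seq(-1.5, 2, length.out = 20)
  cv <- dose_response(p, control = "Kt", grid = grid, method = "tqssa")
  expect_error(hill_number_numeric(cv), "bell")
  bm <- bell_metrics_kt(cv)
  expect_gt(bm$ratio, 1)
  expect_false(bm$boundary)
})

test_that("monotone Kt sweeps give a bell ratio of one within refinement tolerance", {
  p <- pdc_fixture("fig5a_basic")
  grid <- 10^seq(-1, 3, length.out = 60)
  cv <- dose_response(p, control = "Kt", grid = grid, method = "analytic")
  bm <- suppressWarnings(bell_metrics_kt(cv))
  expect_true(bm$boundary)   # monotone: maximum at the top of the grid
  expect_equal(bm$ratio, 1, tolerance = 1e-2)
})

test_that("St-sweep bell metrics classify the printed regimes", {
  sweep <- function(nm) {
    p <- pdc_fixture(nm)
    grid <- 10^seq(-1, 7, length.out = 300)
    dose_response(p, control = "St", grid = grid, method = "analytic")
  }
  ## just above Pt/Kt = alpha: significant bell
  b1 <- bell_metrics_st(sweep("fig4a_p1001"))
  expect_true(b1$bell)
  expect_gt(b1$ratio, 1.05)
  ## well above the line: monotone decay to zero, no significant bell
  b2 <- bell_metrics_st(sweep("fig4a_p2"))
  expect_lt(abs(b2$ratio - 1), 0.05)
  ## below the line: monotone rise towards full phosphorylation
  cv3 <- sweep("fig4a_p08")
  b3 <- suppressWarnings(bell_metrics_st(cv3))
  expect_false(b3$bell)
  expect_gt(max(cv3$R), 0.99)
})

test_that("small-St reference level is stable under halving", {
  p <- pdc_fixture("fig4a_p1001")
  M1 <- derive_constants(p)$M1
  r0 <- function(st) { q <- p; q$St <- st; r_from_sk(solve_sk(q), q) }
  base <- 1e-6 * min(p$Pt, M1)
  expect_lt(abs(r0(base) - r0(base / 2)) / r0(base), 1e-4)
})

test_that("grid refinement leaves Hill and bell metrics essentially unchanged", {
  p <- pdc_fixture("fig4a_p1001")
  ratio_at <- function(n) {
    grid <- 10^seq(-1, 7, length.out = n)
    bell_metrics_st(dose_response(p, control = "St", grid = grid,
                                  method = "analytic"))$ratio
  }
  expect_lt(abs(ratio_at(400) - ratio_at(200)) / ratio_at(200), 0.01)

  pb <- pdc_fixture("fig5a_basic")
  h <- hill_number_analytic(pb)
  nh_at <- function(n) {
    grid <- 10^seq(log10(h$Kt10) - 1.5, log10(h$Kt90) + 1.5, length.out = n)
    cv <- dose_response(pb, control = "Kt", grid = grid, method = "analytic")
    hill_number_numeric(cv, R_inf = h$R_inf)$nH
  }
  expect_lt(abs(nh_at(300) - nh_at(150)) / nh_at(150), 0.01)
})

test_that("2-D scans honour the derived-axis conventions and limits", {
  base <- pdc_fixture("fig3a")
  sc <- scan_2d(base,
                axis1 = list(name = "St_over_Pt", grid = 10^seq(-1, 4, length.out = 8)),
                axis2 = list(name = "lambda1_over_lambda2", grid = 10^seq(-1, 4, length.out = 8)),
                metric = "R_inf")
  expect_true(all(is.finite(sc$metric)))
  ## R_inf -> 1 along the St/Pt -> infinity edge (at moderate lambda1/lambda2)
  edge_st <- sc$metric[sc$value1 == max(sc$value1) & sc$value2 == min(sc$value2)]
  expect_gt(edge_st, 0.99)
  ## R_inf -> alpha/(alpha+1) along the lambda1/lambda2 -> infinity edge
  alpha <- derive_constants(base)$alpha
  v1_near10 <- sc$value1[which.min(abs(sc$value1 - 10))]
  edge_l <- sc$metric[sc$value2 == max(sc$value2) & sc$value1 == v1_near10]
  expect_equal(edge_l, alpha / (alpha + 1), tolerance = 0.05)

  expect_error(scan_2d(base, axis1 = list(name = "bogus", grid = 1),
                       axis2 = list(name = "Pt", grid = 1)), "unknown axis")
})

test_that("the bell mask sits above the Pt/Kt = alpha line only", {
  base <- pdc_fixture("fig4b")
  alphas <- 10^seq(-1.5, 0, length.out = 4)
  ratios <- 10^seq(-2, 0.8, length.out = 9)
  sc <- scan_2d(base,
                axis1 = list(name = "alpha", grid = alphas),
                axis2 = list(name = "Pt_over_Kt", grid = ratios),
                metric = "bell_st", threshold = 1.05, st_grid_n = 150)
  below <- sc$value2 < sc$value1          # Pt/Kt < alpha
  expect_false(any(sc$mask[below], na.rm = TRUE))
  expect_true(any(sc$mask[!below], na.rm = TRUE))
})

test_that("raising phosphatase affinity steepens the response while lowering its plateau", {
  base <- pdc_fixture("fig3b")
  ratios <- 10^seq(-1, 3, length.out = 7)   # lambda1/lambda2
  nh <- vapply(ratios, function(r) {
    p <- base; p$lambda1 <- r * p$lambda2
    hill_number_analytic(p)$nH
  }, numeric(1))
  ri <- vapply(ratios, function(r) {
    p <- base; p$lambda1 <- r * p$lambda2
    sk_inf_kt(p)$R_inf
  }, numeric(1))
  expect_true(all(diff(nh) > 0))
  expect_true(all(diff(ri) < 0))
  ## modest ultrasensitivity survives even at very low plateau: push the
  ## plateau near zero via a slow kinase and check nH stays above 1
  lowR <- base; lowR$k2 <- 1e-3; lowR$St <- 1
  expect_lt(sk_inf_kt(lowR)$R_inf, 0.1)
  expect_gt(hill_number_analytic(lowR)$nH, 1)
})

test_that("the bell is most pronounced at weak P-K binding and high phosphatase", {
  sc <- scan_2d(pdc_fixture("fig7"),
                axis1 = list(name = "omega", grid = c(1, 50)),
                axis2 = list(name = "Pt", grid = c(0.5, 2)),
                metric = "bell_kt", kt_grid_n = 15)
  expect_true(all(sc$metric > 1))
  m <- matrix(sc$metric, 2, byrow = TRUE)   # rows: omega; cols: Pt
  expect_true(all(m[2, ] > m[1, ]))         # larger omega, larger relative peak
  expect_true(all(m[, 2] > m[, 1]))         # more phosphatase, larger relative peak
})
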