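## Figure-level reproductions and task runner ---------------------------------

.write_csv12 <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 12))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.sweep1d_rinf <- function(base, axis, grid) {
  purrr::map_dfr(grid, function(v) {
    p <- .apply_axis(base, axis, v)
    tibble(axis = axis, value = v, R_inf = sk_inf_kt(p)$R_inf)
  })
}

.sweep1d_nh <- function(base, axis, grid) {
  purrr::map_dfr(grid, function(v) {
    p <- .apply_axis(base, axis, v)
    nh <- tryCatch(hill_number_analytic(p)$nH, error = function(e) NA_real_)
    tibble(axis = axis, value = v, nH = nh)
  })
}

#' Reproduce the data behind a figure-level analysis
#'
#' Recomputes the curves, scans or trajectories behind each shipped
#' parameter set together with its summary metrics (Hill numbers, bell
#' ratios, peak times).  Returns data tables; plotting is separate and
#' side-effect-free (see [autoplot()] methods).
#'
#' @param tag One of `"fig3a"`, `"fig3b"`, `"fig4a"`, `"fig4b"`, `"fig5a"`,
#'   `"fig5b"`, `"fig6a"`, `"fig6b"`, `"fig7a"`, `"fig7b"`, `"fig8"`,
#'   `"fig9"`.
#' @param n Resolution knob (grid sizes scale with it).
#' @return A list with elements `data` (tibble or list of tibbles) and
#'   `metrics` (one-row tibble), class `pdc_figure`.
#' @export
reproduce_figure <- function(tag, n = 60) {
  tags <- c("fig3a", "fig3b", "fig4a", "fig4b", "fig5a", "fig5b",
            "fig6a", "fig6b", "fig7a", "fig7b", "fig8", "fig9")
  if (!tag %in% tags) {
    abort(paste0("unknown tag '", tag, "'; available: ", paste(tags, collapse = ", ")))
  }
  out <- switch(tag,
    fig3a = {
      base <- pdc_fixture("fig3a")
      grids <- list(St_over_Pt = 10^seq(-2, 4, length.out = n),
                    alpha = 10^seq(-3, 2, length.out = n),
                    lambda1_over_lambda2 = 10^seq(-2, 3, length.out = n))
      data <- purrr::imap_dfr(grids, function(g, a) .sweep1d_rinf(base, a, g))
      list(data = data,
           metrics = tibble(R_inf_baseline = sk_inf_kt(base)$R_inf))
    },
    fig3b = {
      base <- pdc_fixture("fig3b")
      grids <- list(St_over_Pt = 10^seq(-1, 4, length.out = n),
                    alpha = 10^seq(-2, 2, length.out = n),
                    lambda1_over_lambda2 = 10^seq(-2, 3, length.out = n))
      data <- purrr::imap_dfr(grids, function(g, a) .sweep1d_nh(base, a, g))
      list(data = data,
           metrics = tibble(nH_baseline = hill_number_analytic(base)$nH))
    },
    fig4a = {
      fx <- c("fig4a_p1001", "fig4a_p2", "fig4a_p08")
      data <- purrr::map_dfr(fx, function(f) {
        p <- pdc_fixture(f)
        grid <- 10^seq(-1, 7, length.out = 4 * n)
        cv <- dose_response(p, control = "St", grid = grid, method = "analytic")
        dplyr::mutate(as_tibble(cv), fixture = f)
      })
      mets <- purrr::map_dfr(fx, function(f) {
        p <- pdc_fixture(f)
        grid <- 10^seq(-1, 7, length.out = 4 * n)
        cv <- dose_response(p, control = "St", grid = grid, method = "analytic")
        dplyr::mutate(bell_metrics_st(cv), fixture = f)
      })
      list(data = data, metrics = mets)
    },
    fig4b = {
      base <- pdc_fixture("fig4b")
      sc <- scan_2d(base,
                    axis1 = list(name = "alpha", grid = 10^seq(-2, 1, length.out = max(7, n %/% 6))),
                    axis2 = list(name = "Pt_over_Kt", grid = 10^seq(-2.5, 0.5, length.out = max(9, n %/% 5))),
                    metric = "bell_st", threshold = 1.05)
      list(data = sc, metrics = tibble(n_masked = sum(sc$mask, na.rm = TRUE)))
    },
    fig5a = .figure_ultra("fig5a_basic", "fig5a_Kactive", n),
    fig5b = .figure_ultra("fig5b_basic", "fig5b_Pactive", n),
    fig6a = .figure_bell6("fig6a", n),
    fig6b = .figure_bell6("fig6b", n),
    fig7a = {
      base <- pdc_fixture("fig7")
      sc <- scan_2d(base,
                    axis1 = list(name = "omega", grid = 10^seq(-1, 2, length.out = max(5, n %/% 12))),
                    axis2 = list(name = "Pt", grid = 10^seq(-1, 1, length.out = max(5, n %/% 12))),
                    metric = "bell_kt", kt_grid_n = 30)
      list(data = sc, metrics = tibble(max_ratio = max(sc$metric, na.rm = TRUE)))
    },
    fig7b = {
      base <- pdc_fixture("fig7")
      sc <- scan_2d(base,
                    axis1 = list(name = "omega", grid = 10^seq(-1, 2, length.out = max(5, n %/% 12))),
                    axis2 = list(name = "M3", grid = 10^seq(0, 3, length.out = max(5, n %/% 12))),
                    metric = "bell_kt", kt_grid_n = 30)
      list(data = sc, metrics = tibble(max_ratio = max(sc$metric, na.rm = TRUE)))
    },
    fig8 = {
      kts <- 10^seq(-1.3, 1, length.out = max(8, n %/% 6))
      data <- purrr::map_dfr(c("fig8_basic", "fig8_extended"), function(f) {
        p <- pdc_fixture(f)
        purrr::map_dfr(kts, function(k) {
          p$Kt <- k
          tibble(fixture = f, Kt = k,
                 transient_time = transient_time(p, tol = 1e-4))
        })
      })
      peak <- data |> dplyr::group_by(.data$fixture) |>
        dplyr::summarise(Kt_at_max = .data$Kt[which.max(.data$transient_time)],
                         max_time = max(.data$transient_time))
      list(data = data, metrics = peak)
    },
    fig9 = {
      rec <- simulate_recruitment(pdc_fixture("fig9_recruitment"),
                                  rate = 3e-4, t_end = 20000, n = 4000)
      tri <- simulate_trigger(pdc_fixture("fig9_trigger"),
                              post = list(lambda3 = 10, lambda_m3 = 10, k3 = 500),
                              switch_time = 300, t_end = 2000, n = 2000)
      mets <- dplyr::bind_rows(
        dplyr::mutate(attr(rec, "peak"), scenario = "recruitment"),
        dplyr::mutate(attr(tri, "peak"), scenario = "trigger"))
      list(data = list(recruitment = rec, trigger = tri), metrics = mets)
    })
  out$tag <- tag
  class(out) <- "pdc_figure"
  out
}

.figure_ultra <- function(basic_fix, ext_fix, n) {
  pb <- pdc_fixture(basic_fix); pe <- pdc_fixture(ext_fix)
  grid <- 10^seq(-2, 3, length.out = n) * pb$Pt
  cb <- dose_response(pb, control = "Kt", grid = grid, method = "analytic")
  ce <- dose_response(pe, control = "Kt", grid = grid, method = "ode")
  rinf_e <- steady_state(.set_pool(pe, "Kt", 1e5 * pe$Pt))$R
  data <- dplyr::bind_rows(dplyr::mutate(as_tibble(cb), model = "basic"),
                           dplyr::mutate(as_tibble(ce), model = "extended"))
  metrics <- tibble(
    nH_basic = hill_number_analytic(pb)$nH,
    nH_extended = hill_number_numeric(ce, R_inf = rinf_e)$nH)
  list(data = data, metrics = metrics)
}

.figure_bell6 <- function(fix, n) {
  pe <- pdc_fixture(fix)
  pb <- pe
  pb[c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1")] <- 0
  pb$variant <- "basic"
  grid <- 10^seq(-2.5, 2.5, length.out = n)
  cb <- dose_response(pb, control = "Kt", grid = grid, method = "analytic")
  ce <- dose_response(pe, control = "Kt", grid = grid, method = "ode")
  ct <- dose_response(pe, control = "Kt", grid = grid, method = "tqssa")
  data <- dplyr::bind_rows(dplyr::mutate(as_tibble(cb), model = "basic"),
                           dplyr::mutate(as_tibble(ce), model = "extended"),
                           dplyr::mutate(as_tibble(ct), model = "tqssa"))
  metrics <- tibble(
    nH_basic = hill_number_analytic(pb)$nH,
    bell_ratio_ode = bell_metrics_kt(ce)$ratio,
    bell_ratio_tqssa = bell_metrics_kt(ct)$ratio)
  list(data = data, metrics = metrics)
}

#' Run a configured task
#'
#' Thin dispatcher tying the modules together for scripted use.  The config
#' is a named list (or path to a JSON file of one) with exactly one
#' parameter source (`fixture` name or inline `params` block) and a `task`:
#' `"simulate"`, `"steady"`, `"dose_response"`, `"hill"`, `"bell"`,
#' `"scan2d"`, `"tqssa"`, `"scenario"` or `"reproduce_figure"`.  Remaining
#' entries are task options.  If `out` is given, tabular results are
#' written there as CSV (12 significant digits) and one-row results as
#' JSON; the resolved config is attached to the return value as a manifest.
#'
#' @param config Named list or JSON file path.
#' @return Task result (tibble or list), with attribute `"manifest"`.
#' @export
run_task <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.null(config$fixture) && !is.null(config$params)) {
    abort("config must have exactly one of `fixture` or `params`")
  }
  params <- if (!is.null(config$fixture)) pdc_fixture(config$fixture)
            else if (!is.null(config$params)) do.call(pdc_params, config$params)
            else if (identical(config$task, "reproduce_figure")) NULL
            else abort("config needs a `fixture` or `params` block")
  task <- config$task %||% abort("config needs a `task`")
  res <- switch(task,
    simulate = pdc_integrate(params, times = seq(0, config$t_end %||% 100,
                                                 length.out = config$n %||% 500)),
    steady = steady_state(params),
    dose_response = dose_response(params, control = config$control %||% "Kt",
                                  method = config$method %||% "ode",
                                  n = config$n %||% 200),
    hill = {
      if (params$variant == "basic") hill_number_analytic(params)
      else {
        cv <- dose_response(params, control = "Kt", method = "ode",
                            n = config$n %||% 120)
        hill_number_numeric(cv)
      }
    },
    bell = {
      cv <- dose_response(params, control = config$control %||% "Kt",
                          method = config$method %||% "ode", n = config$n %||% 120)
      if ((config$control %||% "Kt") == "Kt") bell_metrics_kt(cv) else bell_metrics_st(cv)
    },
    scan2d = scan_2d(params, axis1 = config$axis1, axis2 = config$axis2,
                     metric = config$metric %||% "R_inf",
                     threshold = config$threshold %||% 1.05),
    tqssa = tqssa_steady_state(params, Kt = config$Kt %||%
                                 .default_grid(params, "Kt", config$n %||% 100)),
    scenario = {
      if (!is.null(config$recruitment_rate_uM_per_s)) {
        simulate_recruitment(params, rate = config$recruitment_rate_uM_per_s,
                             t_end = config$t_end %||% 20000)
      } else {
        simulate_trigger(params, post = config$post_switch,
                         switch_time = config$switch_time_s,
                         t_end = config$t_end %||% 2000)
      }
    },
    reproduce_figure = reproduce_figure(config$tag),
    abort(paste0("unknown task '", task, "'")))
  attr(res, "manifest") <- config
  if (!is.null(config$out) && is.data.frame(res)) {
    if (nrow(res) == 1) {
      jsonlite::write_json(as.list(res), config$out, auto_unbox = TRUE, digits = NA)
    } else .write_csv12(as.data.frame(res), config$out)
  }
  res
}
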