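## Parameter model -----------------------------------------------------------
##
## A parameter set is a one-row tibble with all mass-action rate constants,
## the three conserved pools and the model variant, so that collections of
## parameter sets stack into ordinary tibbles and map cleanly over rows.

.pdc_rate_names <- c(
  "lambda1", "lambda_m1", "k1",     # phosphatase arm: Sp + P <-> SpP -> S + P
  "lambda2", "lambda_m2", "k2",     # kinase arm:      S + K <-> SK  -> Sp + K
  "lambda3", "lambda_m3", "k3",     # complex phosphatase arm: Sp + PK <-> SpPK -> S + PK
  "lambda4", "lambda_m4", "k4",     # complex kinase arm:      S + PK <-> SPK  -> Sp + PK
  "kappa1", "kappa_m1"              # complex formation:       P + K <-> PK
)
.pdc_pool_names <- c("Kt", "Pt", "St")

#' Model variants of the phosphorylation-dephosphorylation cycle
#'
#' The basic cycle has free kinase and phosphatase only.  The extended model
#' adds a reversible kinase-phosphatase complex `PK`; within the complex each
#' enzyme can be catalytically active or not, giving four extended variants.
#'
#' @return Character vector of the recognised variant tags.
#' @export
pdc_variants <- function() {
  c("basic", "complex_inactive", "complex_P_active",
    "complex_K_active", "complex_both_active")
}

#' Construct a PDC parameter set
#'
#' Units are fixed throughout the package: concentrations in uM, time in s,
#' association rates (`lambda1`, `lambda2`, `lambda3`, `lambda4`, `kappa1`)
#' in 1/(uM s), dissociation (`lambda_m*`, `kappa_m1`) and catalytic (`k*`)
#' rates in 1/s.
#'
#' Arms that the variant declares inactive are zeroed (association and
#' catalysis; dissociation is retained so pre-populated complexes can drain)
#' with a warning, via [validate_variant()].
#'
#' @param lambda1,lambda_m1,k1 Phosphatase arm: `Sp + P <-> SpP -> S + P`.
#' @param lambda2,lambda_m2,k2 Kinase arm: `S + K <-> SK -> Sp + K`.
#' @param lambda3,lambda_m3,k3 Complex phosphatase arm: `Sp + PK <-> SpPK -> S + PK`.
#' @param lambda4,lambda_m4,k4 Complex kinase arm: `S + PK <-> SPK -> Sp + PK`.
#' @param kappa1,kappa_m1 Complex formation: `P + K <-> PK`.
#' @param Kt,Pt,St Total kinase, phosphatase and substrate pools (uM).
#' @param variant One of [pdc_variants()].
#' @return A one-row tibble of class `pdc_params`.
#' @examples
#' p <- pdc_params(lambda1 = 1, lambda_m1 = 1, k1 = 1,
#'                 lambda2 = 1, lambda_m2 = 1, k2 = 1,
#'                 Kt = 10, Pt = 1, St = 100)
#' derive_constants(p)
#' @export
pdc_params <- function(lambda1 = 0, lambda_m1 = 0, k1 = 0,
                       lambda2 = 0, lambda_m2 = 0, k2 = 0,
                       lambda3 = 0, lambda_m3 = 0, k3 = 0,
                       lambda4 = 0, lambda_m4 = 0, k4 = 0,
                       kappa1 = 0, kappa_m1 = 0,
                       Kt = 0, Pt = 0, St = 0,
                       variant = "basic") {
  variant <- match.arg(variant, pdc_variants())
  out <- tibble(
    lambda1 = as.numeric(lambda1), lambda_m1 = as.numeric(lambda_m1), k1 = as.numeric(k1),
    lambda2 = as.numeric(lambda2), lambda_m2 = as.numeric(lambda_m2), k2 = as.numeric(k2),
    lambda3 = as.numeric(lambda3), lambda_m3 = as.numeric(lambda_m3), k3 = as.numeric(k3),
    lambda4 = as.numeric(lambda4), lambda_m4 = as.numeric(lambda_m4), k4 = as.numeric(k4),
    kappa1 = as.numeric(kappa1), kappa_m1 = as.numeric(kappa_m1),
    Kt = as.numeric(Kt), Pt = as.numeric(Pt), St = as.numeric(St),
    variant = variant
  )
  class(out) <- c("pdc_params", class(out))
  assert_params(out)
  validate_variant(out, quiet_if_clean = TRUE)
}

assert_params <- function(params) {
  for (nm in c(.pdc_rate_names, .pdc_pool_names)) {
    v <- params[[nm]]
    if (!is.finite(v) || v < 0) {
      abort(sprintf("parameter `%s` must be finite and >= 0 (got %s)", nm, format(v)))
    }
  }
  invisible(params)
}

## Which arms must be zeroed for each variant.  "Zeroed" means association
## and catalysis; dissociation rates are retained (bound complexes on a
## deactivated arm may still unbind).
.variant_zeroed <- function(variant) {
  switch(variant,
    basic               = c("lambda3", "k3", "lambda4", "k4", "kappa1", "kappa_m1"),
    complex_inactive    = c("lambda3", "k3", "lambda4", "k4"),
    complex_P_active    = c("lambda4", "k4"),
    complex_K_active    = c("lambda3", "k3"),
    complex_both_active = character(0)
  )
}

#' Zero the reaction arms a model variant forbids
#'
#' Returns a copy of `params` whose inactive-arm association and catalytic
#' rates are forced to zero per the variant (for the basic variant also the
#' complex-formation rates).  Dissociation rates of the complex arms are kept
#' so that complexes bound through a deactivated arm can still drain.  A
#' warning names any field that was nonzero and had to be zeroed.
#'
#' @param params A `pdc_params` row.
#' @param variant Variant tag; defaults to `params$variant`.
#' @param quiet_if_clean Internal; suppress the attribute when nothing changed.
#' @return `params` with inactive arms zeroed; attribute `"zeroed"` lists the
#'   fields that were modified.
#' @export
validate_variant <- function(params, variant = params$variant,
                             quiet_if_clean = FALSE) {
  variant <- match.arg(variant, pdc_variants())
  fields <- .variant_zeroed(variant)
  touched <- fields[vapply(fields, function(f) params[[f]] != 0, logical(1))]
  if (length(touched)) {
    warn(sprintf(
      "variant '%s' forbids nonzero %s; zeroing", variant,
      paste0("`", touched, "`", collapse = ", ")))
    params[touched] <- 0
  }
  params$variant <- variant
  attr(params, "zeroed") <- touched
  params
}

#' Derived kinetic constants
#'
#' Computes the catalytic ratio `alpha = k2/k1`, the Michaelis constants
#' `Mi = (lambda_mi + ki)/lambdai` (uM) for each reaction arm and the
#' complex dissociation constant `omega = kappa_m1/kappa1` (uM).  A constant
#' whose defining rate is zero is reported as `NA` rather than an infinity.
#'
#' @param params A `pdc_params` row.
#' @return One-row tibble with columns `alpha`, `M1`..`M4`, `omega`.
#' @export
derive_constants <- function(params) {
  assert_params(params)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    alpha = safe_div(params$k2, params$k1),
    M1 = safe_div(params$lambda_m1 + params$k1, params$lambda1),
    M2 = safe_div(params$lambda_m2 + params$k2, params$lambda2),
    M3 = safe_div(params$lambda_m3 + params$k3, params$lambda3),
    M4 = safe_div(params$lambda_m4 + params$k4, params$lambda4),
    omega = safe_div(params$kappa_m1, params$kappa1)
  )
}

#' Sample random parameter sets
#'
#' Draws each field log-uniformly between its bounds; fields absent from
#' `ranges` keep the value in `base`.  Used for property-style checks of the
#' analytic machinery against the ODE solver.
#'
#' @param ranges Named list; each element `c(lower, upper)` with
#'   `0 < lower <= upper`.  Names must be rate or pool fields.
#' @param n Number of sets to draw.
#' @param seed Integer seed; same seed, same draw.
#' @param base Template `pdc_params` row (default: all-ones basic cycle).
#' @return A tibble of `n` parameter rows (class `pdc_params`).
#' @export
sample_params <- function(ranges, n = 1, seed = 1L, base = NULL) {
  if (is.null(base)) {
    base <- pdc_params(lambda1 = 1, lambda_m1 = 1, k1 = 1,
                       lambda2 = 1, lambda_m2 = 1, k2 = 1,
                       Kt = 1, Pt = 1, St = 1)
  }
  bad <- setdiff(names(ranges), c(.pdc_rate_names, .pdc_pool_names))
  if (length(bad)) abort(paste0("unknown fields in `ranges`: ", paste(bad, collapse = ", ")))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] <= 0 || r[1] > r[2]) {
      abort(sprintf("`ranges$%s` must be c(lower, upper) with 0 < lower <= upper", nm))
    }
  }
  set.seed(as.integer(seed))
  rows <- purrr::map(seq_len(n), function(i) {
    p <- base
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      p[[nm]] <- exp(runif(1, log(r[1]), log(r[2])))
    }
    p
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pdc_params", class(out))
  out
}

## Config serialization -------------------------------------------------------

#' Read / write a flat parameter config
#'
#' The on-disk format is a flat JSON object with keys `lambda1`, `lambda_m1`,
#' `k1`, ..., `kappa1`, `kappa_m1`, `Kt`, `Pt`, `St`, `variant`.  Fixtures
#' round-trip bit-exactly.
#'
#' @param path File path.
#' @return For `read_pdc_config()`, a `pdc_params` row.
#' @export
read_pdc_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c(.pdc_rate_names, .pdc_pool_names, "variant")
  missing <- setdiff(need, names(x))
  if (length(missing)) abort(paste0("config missing keys: ", paste(missing, collapse = ", ")))
  do.call(pdc_params, x[need])
}

#' @rdname read_pdc_config
#' @param params A `pdc_params` row to serialize.
#' @export
write_pdc_config <- function(params, path) {
  x <- as.list(params[1, c(.pdc_rate_names, .pdc_pool_names, "variant")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pdc_params <- function(x, ...) {
  cat(sprintf("<pdc_params: %d set(s)>\n", nrow(x)))
  NextMethod()
}
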