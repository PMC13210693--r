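# broom-style accessors for fitted objects.

tidy_foce <- function(x) {
  style <- x$coding$param_style
  scale <- c(
    tvcl = "L/h", tvv = "L", omega2_cl = "variance (log scale)",
    omega2_v = "variance (log scale)",
    sigma1 = "variance", sigma2 = "variance",
    theta4 = "SD or CV", theta5 = "SD"
  )
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    scale = unname(scale[x$terms])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a FOCE-I fit
#'
#' One row per estimated parameter, on the reporting scale: SIGMA entries as
#' variances, THETA entries as standard deviations (or CV fractions for
#' proportional terms), with delta-method standard errors.
#'
#' @param x A `foce_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `scale`.
#' @method tidy foce_fit
#' @export
tidy.foce_fit <- function(x, ...) {
  tidy_foce(x)
}

#' One-row summary of a FOCE-I fit
#'
#' @inheritParams tidy.foce_fit
#' @return Tibble with `coding`, `ofv`, `n_subjects`, `n_obs`, `converged`,
#'   `ofv_evals`, `grad_norm`, plus the derived residual-error summaries
#'   `ruv_sd` (additive SD, mg/L, where defined) and `ruv_cv` (proportional
#'   CV fraction, where defined).
#' @method glance foce_fit
#' @export
glance.foce_fit <- function(x, ...) {
  drv <- derived_ruv(x)
  tibble::tibble(
    coding = x$coding$id, ofv = x$ofv,
    n_subjects = x$n_subjects, n_obs = x$n_obs,
    converged = x$convergence$success,
    ofv_evals = x$convergence$ofv_evals,
    grad_norm = x$convergence$grad_norm,
    ruv_cv = drv$cv, ruv_sd = drv$sd
  )
}

# Residual-error estimates on the SD/CV scale, whichever the coding defines.
derived_ruv <- function(fit) {
  e <- fit$estimates
  switch(fit$coding$id,
    ADD.1 = ,
    ADD.2 = list(cv = NA_real_, sd = sqrt(e[["sigma1"]])),
    ADD.3 = list(cv = NA_real_, sd = e[["theta4"]]),
    PROP.1 = ,
    PROP.2 = list(cv = sqrt(e[["sigma1"]]), sd = NA_real_),
    PROP.3 = list(cv = e[["theta4"]], sd = NA_real_),
    COMB_VAR1 = list(cv = sqrt(e[["sigma1"]]), sd = sqrt(e[["sigma2"]])),
    COMB_VAR3 = ,
    COMB_SD = list(cv = e[["theta4"]], sd = e[["theta5"]])
  )
}

#' Diagnostics table of a fit
#'
#' Computes the full [nm_diagnostics()] table at the fitted parameter point.
#'
#' @inheritParams tidy.foce_fit
#' @return An `nm_diag` tibble.
#' @method augment foce_fit
#' @export
augment.foce_fit <- function(x, ...) {
  nm_diagnostics(x$data, x$params, x$coding)
}
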