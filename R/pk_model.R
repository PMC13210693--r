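# One-compartment, first-order oral absorption, parameterized as CL/F, V/F, KA.
# Closed form:
#   C(t) = dose * ka / (V (ka - ke)) * (exp(-ke t) - exp(-ka t)),  ke = CL/V
# evaluated in the numerically stable form
#   C(t) = dose * ka / V * exp(-ka t) * t * expm1(u)/u,            u = (ka - ke) t
# which passes smoothly through the flip-flop point ka = ke, where the
# limit is C(t) = dose * ka * t * exp(-ka t) / V.

check_pos <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("invalid parameter: `", what, "` must be strictly positive and finite"),
      class = "ruvdiag_invalid_parameter"
    )
  }
  invisible(x)
}

#' Concentration of a one-compartment first-order oral absorption model
#'
#' Closed-form plasma concentration after a single oral dose, parameterized in
#' apparent clearance (CL/F), apparent volume (V/F) and the absorption rate
#' constant KA. The degenerate case `ka == cl/v` (flip-flop point) is handled
#' by the analytic limit, so the function is continuous in the parameters.
#'
#' @param t Time after dose (h); vector, values must be `>= 0`.
#' @param dose Dose amount (mg); scalar or vector recycled against `t`.
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent volume of distribution V/F (L).
#' @param ka Absorption rate constant (1/h).
#' @return Concentration (mg/L), same length as the recycled arguments.
#' @examples
#' pk_conc(c(0, 2, 24), dose = 100, cl = 5, v = 50, ka = 1)
#' @export
pk_conc <- function(t, dose, cl, v, ka) {
  check_pos(dose, "dose")
  check_pos(cl, "cl")
  check_pos(v, "v")
  check_pos(ka, "ka")
  if (any(t < 0)) abort("`t` must be non-negative", class = "ruvdiag_invalid_parameter")
  ke <- cl / v
  u <- (ka - ke) * t
  # expm1(u)/u -> 1 as u -> 0; guard the 0/0 form explicitly
  fac <- ifelse(abs(u) < .Machine$double.xmin, t, t * expm1(u) / ifelse(u == 0, 1, u))
  dose * ka / v * exp(-ka * t) * fac
}

#' Time of maximum concentration
#'
#' `ln(ka/ke) / (ka - ke)` with `ke = cl/v`; at the flip-flop point the limit
#' `1/ka` is returned.
#'
#' @inheritParams pk_conc
#' @return Time of the concentration maximum (h).
#' @export
pk_tmax <- function(cl, v, ka) {
  check_pos(cl, "cl")
  check_pos(v, "v")
  check_pos(ka, "ka")
  ke <- cl / v
  ifelse(abs(ka - ke) < 1e-12 * ka, 1 / ka, log(ka / ke) / (ka - ke))
}

# g(u) = (expm1(u) - u exp(u)) / u^2, the stable kernel of dC/dke.
# Series for small |u|: -(1/2 + u/3 + u^2/8 + u^3/30 + ...).
dcdke_kernel <- function(u) {
  small <- is.finite(u) & abs(u) < 1e-4
  out <- numeric(length(u))
  us <- u[small]
  out[small] <- -(1 / 2 + us / 3 + us^2 / 8 + us^3 / 30)
  ub <- u[!small]
  out[!small] <- (expm1(ub) - ub * exp(ub)) / ub^2
  out
}

# Row-wise concentration and d/deta sensitivities for individual parameters
# cl = tvcl exp(eta_cl), v = tvv exp(eta_v). Everything vectorized over rows.
pk_conc_grad <- function(t, dose, cl, v, ka) {
  ke <- cl / v
  u <- (ka - ke) * t
  e2 <- exp(-ka * t)
  a <- dose * ka / v
  conc <- a * e2 * ifelse(abs(u) < .Machine$double.xmin, t,
    t * expm1(u) / ifelse(u == 0, 1, u)
  )
  dcdke <- a * t^2 * e2 * dcdke_kernel(u)
  # d ke/d eta_cl = ke ; d ke/d eta_v = -ke ; d(1/v)/d eta_v brings -C
  j_cl <- ke * dcdke
  j_v <- -conc - ke * dcdke
  list(conc = conc, j_cl = j_cl, j_v = j_v)
}

#' Analytic sensitivities of the concentration to the random effects
#'
#' Jacobian of the individual concentration profile with respect to the
#' between-subject random effects `eta = (eta_cl, eta_v)`, where
#' `cl = tvcl * exp(eta_cl)` and `v = tvv * exp(eta_v)`. Used by the FOCE
#' linearization; analytic rather than finite-difference so that the
#' linearized likelihood is exact to machine precision.
#'
#' @param times Observation times (h), nonempty vector.
#' @param dose Dose amount (mg).
#' @param struct Named numeric vector with elements `tvcl`, `tvv`, `ka`.
#' @param eta Length-2 numeric vector `(eta_cl, eta_v)` at which to evaluate.
#' @return A `length(times) x 2` matrix with columns `eta_cl`, `eta_v`.
#' @examples
#' pk_eta_jacobian(c(1, 4, 24), 100, c(tvcl = 5, tvv = 50, ka = 1), c(0, 0))
#' @export
pk_eta_jacobian <- function(times, dose, struct, eta = c(0, 0)) {
  if (length(times) == 0) abort("`times` must be nonempty", class = "ruvdiag_invalid_parameter")
  stopifnot(length(eta) == 2)
  cl <- struct[["tvcl"]] * exp(eta[[1]])
  v <- struct[["tvv"]] * exp(eta[[2]])
  g <- pk_conc_grad(times, dose, cl, v, struct[["ka"]])
  cbind(eta_cl = g$j_cl, eta_v = g$j_v)
}

# Internal model abstraction used by the FOCE engine. `predict`/`jacobian`
# take per-row eta matrices so the engine can evaluate all subjects at once.
model_spec <- function(n_eta, predict, jacobian, eta_names) {
  structure(
    list(n_eta = n_eta, predict = predict, jacobian = jacobian, eta_names = eta_names),
    class = "ruv_model"
  )
}

pk_model_spec <- function() {
  model_spec(
    n_eta = 2,
    predict = function(struct, eta_rows, time, amt) {
      cl <- struct[["tvcl"]] * exp(eta_rows[, 1])
      v <- struct[["tvv"]] * exp(eta_rows[, 2])
      pk_conc_grad(time, amt, cl, v, struct[["ka"]])$conc
    },
    jacobian = function(struct, eta_rows, time, amt) {
      cl <- struct[["tvcl"]] * exp(eta_rows[, 1])
      v <- struct[["tvv"]] * exp(eta_rows[, 2])
      g <- pk_conc_grad(time, amt, cl, v, struct[["ka"]])
      cbind(g$j_cl, g$j_v)
    },
    eta_names = c("eta_cl", "eta_v")
  )
}
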