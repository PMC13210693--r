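# NONMEM-style diagnostic residuals.
#
# Individual (conditional): IPRED = f(etahat), IRES = DV - IPRED,
#   IWRES = IRES / W(IPRED)  -- W is the coding's diagnostic scale, the
#   only place the user-defined W enters.
# Population (first order):  PRED = f(0), RES = DV - PRED,
#   WRES_i = L0^-1 (y_i - PRED_i),  V0 = J(0) Omega J(0)' + diag(v(PRED)),
# Conditional with interaction:
#   CWRESI_i = L^-1 (y_i - E_i),  E = f(etahat) - J(etahat) etahat,
#   V = J(etahat) Omega J(etahat)' + diag(v(f(etahat))).
# L is the lower-triangular Cholesky factor (forward substitution), the
# standard decorrelation convention; per-observation values depend on this
# choice, summary statistics do not.

diag_cols <- c("ID", "TIME", "DV", "IPRED", "IWRES", "WRES", "CWRESI", "PRED", "RES")

whiten_by_subject <- function(prep, jac, omega2, v, resid) {
  out <- numeric(prep$n_obs)
  k <- ncol(jac)
  omega <- diag(omega2, k)
  idx <- split(seq_len(prep$n_obs), prep$subj)
  for (s in seq_along(idx)) {
    ii <- idx[[s]]
    j_i <- jac[ii, , drop = FALSE]
    v_i <- j_i %*% omega %*% t(j_i)
    diag(v_i) <- diag(v_i) + v[ii]
    lt <- tryCatch(t(chol(v_i)), error = function(e) {
      abort(paste0("marginal covariance not positive definite (subject ", prep$ids[s], ")"),
        class = "ruvdiag_numerical_error"
      )
    })
    out[ii] <- forwardsolve(lt, resid[ii])
  }
  out
}

diag_compute <- function(data, pop, coding) {
  stopifnot(inherits(pop, "pop_params"), inherits(coding, "error_coding"))
  model <- pk_model_spec()
  prep <- prep_nm(data)
  omega2 <- unname(pop$omega2)
  ep <- pop$err

  inner <- inner_newton(prep, model, pop$struct, omega2, coding, ep)
  er <- inner$eta[prep$subj, , drop = FALSE]

  ipred <- model$predict(pop$struct, er, prep$time, prep$amt)
  ires <- prep$y - ipred
  w <- coding$w_fn(ipred, ep)
  iwres <- ires / w
  if (any(w == 0)) {
    warn(paste0(sum(w == 0), " observation(s) have W = 0; IWRES undefined there"))
    iwres[w == 0] <- NA_real_
  }

  zero <- matrix(0, prep$n_obs, model$n_eta)
  pred <- model$predict(pop$struct, zero, prep$time, prep$amt)
  res <- prep$y - pred
  j0 <- model$jacobian(pop$struct, zero, prep$time, prep$amt)
  v0 <- coding$variance_fn(pred, ep)
  wres <- whiten_by_subject(prep, j0, omega2, v0, res)

  jhat <- model$jacobian(pop$struct, er, prep$time, prep$amt)
  vhat <- coding$variance_fn(ipred, ep)
  cres <- prep$y - (ipred - rowSums(jhat * er))
  cwresi <- whiten_by_subject(prep, jhat, omega2, vhat, cres)

  out <- tibble::tibble(
    ID = prep$obs$ID, TIME = prep$time, DV = prep$y,
    IPRED = ipred, IWRES = iwres, WRES = wres, CWRESI = cwresi,
    PRED = pred, RES = res, IRES = ires, W = w
  )
  class(out) <- c("nm_diag", class(out))
  attr(out, "coding_id") <- coding$id
  attr(out, "params") <- pop
  out
}

#' Full diagnostics table for a parameter point or fit
#'
#' Computes the complete per-observation diagnostics table: `ID, TIME, DV,
#' IPRED, IWRES, WRES, CWRESI, PRED, RES` (plus `IRES` and `W`). Empirical
#' Bayes etas are estimated internally at the supplied parameter point, so the
#' table can be produced for any coding/parameter combination, not only at a
#' fitted optimum — holding the parameters fixed and swapping the coding
#' isolates the pure effect of the W definition.
#'
#' @inheritParams estimate_etas
#' @return A tibble of class `nm_diag` with one row per observation;
#'   attributes `coding_id` and `params` record the provenance.
#' @examples
#' ds <- simulate_dataset(sim_protocol("additive", n_subjects = 5, seed = 1))
#' pop <- pop_params(5, 50, omega2_cl = 0.09, omega2_v = 0.09, err = err_params(sigma1 = 0.25))
#' nm_diagnostics(ds, pop, error_coding("ADD.1"))
#' @export
nm_diagnostics <- function(data, pop, coding) {
  diag_compute(data, pop, coding)
}

#' Component residual sets
#'
#' Thin wrappers around [nm_diagnostics()] returning the individual
#' (conditional) residuals `IPRED, IRES, IWRES`, the population (first-order)
#' residuals `PRED, RES, WRES`, or the conditional weighted residuals with
#' interaction `CWRESI`.
#'
#' @inheritParams estimate_etas
#' @return A tibble with `ID`, `TIME` and the respective residual columns.
#' @name residual_components
NULL

#' @rdname residual_components
#' @export
individual_residuals <- function(data, pop, coding) {
  diag_compute(data, pop, coding)[, c("ID", "TIME", "IPRED", "IRES", "IWRES")]
}

#' @rdname residual_components
#' @export
population_residuals <- function(data, pop, coding) {
  diag_compute(data, pop, coding)[, c("ID", "TIME", "PRED", "RES", "WRES")]
}

#' @rdname residual_components
#' @export
conditional_residuals <- function(data, pop, coding) {
  diag_compute(data, pop, coding)[, c("ID", "TIME", "CWRESI")]
}

#' Epsilon-shrinkage
#'
#' `1 - SD(IWRES)` (sample SD, denominator `n - 1`). Shrinkage of the
#' empirical Bayes etas compresses individual residuals towards zero, so even
#' a correctly normalized IWRES has an SD slightly below 1; this statistic
#' quantifies that compression.
#'
#' @param iwres Numeric vector of IWRES values, or an `nm_diag` table.
#' @return Shrinkage as a fraction (e.g. `0.053` for SD(IWRES) = 0.947).
#' @examples
#' epsilon_shrinkage(c(-0.947, 0.947) / sqrt(2)) # a column with SD exactly 0.947
#' @export
epsilon_shrinkage <- function(iwres) {
  if (inherits(iwres, "nm_diag")) iwres <- iwres$IWRES
  iwres <- iwres[!is.na(iwres)]
  if (length(iwres) < 2) abort("need at least two IWRES values", class = "ruvdiag_configuration_error")
  1 - sd(iwres)
}

#' Write a diagnostics table as CSV
#'
#' Writes exactly the canonical column set and order
#' `ID, TIME, DV, IPRED, IWRES, WRES, CWRESI, PRED, RES`.
#'
#' @param table An `nm_diag` tibble.
#' @param path Output file.
#' @export
write_diagnostics <- function(table, path) {
  readr::write_csv(table[, diag_cols], path)
  invisible(path)
}
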