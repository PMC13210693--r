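# The nine $ERROR-block coding variants. Each coding separates
#  * variance_fn: the residual variance entering the likelihood (implied by Y)
#  * w_fn:        the user-defined diagnostic scale used only for IWRES = IRES/W
# For "normalized" codings w_fn^2 == variance_fn identically; the
# non-normalized codings (W = 1, W = IPRED) omit the estimated variance
# component from W, which is the artifact under study.

#' Residual error parameters
#'
#' Container for the residual-error parameters of an error coding. SIGMA-style
#' parameters (`sigma1`, `sigma2`) live on the variance scale; THETA-style
#' parameters (`theta4`, `theta5`) on the standard-deviation scale, mirroring
#' NONMEM conventions (`$SIGMA` entries vs `THETA(4)/THETA(5)` with
#' `$SIGMA 1 FIX`). Only the slots used by a given coding need to be supplied.
#'
#' @param sigma1,sigma2 Variance-scale parameters (first and second `EPS`).
#' @param theta4,theta5 SD-scale parameters.
#' @return An object of class `err_params`.
#' @examples
#' err_params(sigma1 = 0.216)
#' err_params(theta4 = 0.15, theta5 = 0.5)
#' @export
err_params <- function(sigma1 = NULL, sigma2 = NULL, theta4 = NULL, theta5 = NULL) {
  p <- list(sigma1 = sigma1, sigma2 = sigma2, theta4 = theta4, theta5 = theta5)
  for (nm in names(p)) {
    if (!is.null(p[[nm]])) {
      if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) || p[[nm]] <= 0) {
        abort(paste0("`", nm, "` must be a single positive number"),
          class = "ruvdiag_configuration_error"
        )
      }
    }
  }
  structure(p, class = "err_params")
}

# Access an error parameter slot, erroring if the coding does not use it.
p_get <- function(p, name) {
  val <- p[[name]]
  if (is.null(val)) {
    abort(paste0("error parameter `", name, "` is not set but is required by this coding"),
      class = "ruvdiag_configuration_error"
    )
  }
  val
}

new_coding <- function(id, error_type, param_style, n_eps, fixed_sigma, active,
                       variance_fn, w_fn, dvar_fn, y_label, w_label) {
  structure(
    list(
      id = id, error_type = error_type, param_style = param_style,
      n_eps = n_eps, fixed_sigma = fixed_sigma, active = active,
      variance_fn = variance_fn, w_fn = w_fn, dvar_fn = dvar_fn,
      y_label = y_label, w_label = w_label
    ),
    class = "error_coding"
  )
}

#' Registry of the nine residual-error coding variants
#'
#' Returns the nine coding variants: three per residual-error structure
#' (additive, proportional, combined), covering normalized SIGMA-based,
#' non-normalized, and THETA-based (SD-scale, `$SIGMA 1 FIX`) styles. For the
#' combined structure the variants are the two-EPS variance method (`COMB_VAR1`),
#' the one-EPS variance method (`COMB_VAR3`), and the SD method (`COMB_SD`)
#' whose W is a linear function of IPRED, an approximation to the combined
#' standard deviation that degrades at low predicted concentrations.
#'
#' @return Named list of `error_coding` objects, in the canonical run order
#'   `ADD.1, ADD.2, ADD.3, PROP.1, PROP.2, PROP.3, COMB_VAR1, COMB_VAR3, COMB_SD`.
#' @examples
#' names(error_codings())
#' error_coding("PROP.2")
#' @export
error_codings <- function() {
  list(
    ADD.1 = new_coding("ADD.1", "additive", "sigma", 1, FALSE, "sigma1",
      variance_fn = function(ipred, p) rep_len(p_get(p, "sigma1"), length(ipred)),
      w_fn = function(ipred, p) rep_len(sqrt(p_get(p, "sigma1")), length(ipred)),
      dvar_fn = function(ipred, p) rep_len(0, length(ipred)),
      y_label = "Y = IPRED + ERR(1)", w_label = "W = SQRT(SIGMA(1,1))"
    ),
    ADD.2 = new_coding("ADD.2", "additive", "sigma", 1, FALSE, "sigma1",
      variance_fn = function(ipred, p) rep_len(p_get(p, "sigma1"), length(ipred)),
      w_fn = function(ipred, p) rep_len(1, length(ipred)),
      dvar_fn = function(ipred, p) rep_len(0, length(ipred)),
      y_label = "Y = IPRED + W*ERR(1)", w_label = "W = 1"
    ),
    ADD.3 = new_coding("ADD.3", "additive", "theta", 1, TRUE, "theta4",
      variance_fn = function(ipred, p) rep_len(p_get(p, "theta4")^2, length(ipred)),
      w_fn = function(ipred, p) rep_len(p_get(p, "theta4"), length(ipred)),
      dvar_fn = function(ipred, p) rep_len(0, length(ipred)),
      y_label = "Y = IPRED + W*ERR(1)", w_label = "W = THETA(4)"
    ),
    PROP.1 = new_coding("PROP.1", "proportional", "sigma", 1, FALSE, "sigma1",
      variance_fn = function(ipred, p) ipred^2 * p_get(p, "sigma1"),
      w_fn = function(ipred, p) ipred * sqrt(p_get(p, "sigma1")),
      dvar_fn = function(ipred, p) 2 * ipred * p_get(p, "sigma1"),
      y_label = "Y = IPRED + IPRED*ERR(1)", w_label = "W = SQRT(IPRED**2 * SIGMA(1,1))"
    ),
    PROP.2 = new_coding("PROP.2", "proportional", "sigma", 1, FALSE, "sigma1",
      variance_fn = function(ipred, p) ipred^2 * p_get(p, "sigma1"),
      w_fn = function(ipred, p) ipred + numeric(length(ipred)),
      dvar_fn = function(ipred, p) 2 * ipred * p_get(p, "sigma1"),
      y_label = "Y = IPRED + IPRED*ERR(1)", w_label = "W = IPRED"
    ),
    PROP.3 = new_coding("PROP.3", "proportional", "theta", 1, TRUE, "theta4",
      variance_fn = function(ipred, p) ipred^2 * p_get(p, "theta4")^2,
      w_fn = function(ipred, p) ipred * p_get(p, "theta4"),
      dvar_fn = function(ipred, p) 2 * ipred * p_get(p, "theta4")^2,
      y_label = "Y = IPRED + W*ERR(1)", w_label = "W = IPRED * THETA(4)"
    ),
    COMB_VAR1 = new_coding("COMB_VAR1", "combined", "sigma", 2, FALSE, c("sigma1", "sigma2"),
      variance_fn = function(ipred, p) ipred^2 * p_get(p, "sigma1") + p_get(p, "sigma2"),
      w_fn = function(ipred, p) sqrt(ipred^2 * p_get(p, "sigma1") + p_get(p, "sigma2")),
      dvar_fn = function(ipred, p) 2 * ipred * p_get(p, "sigma1"),
      y_label = "Y = IPRED + IPRED*ERR(1) + ERR(2)",
      w_label = "W = SQRT(IPRED**2 * SIGMA(1,1) + SIGMA(2,2))"
    ),
    COMB_VAR3 = new_coding("COMB_VAR3", "combined", "theta", 1, TRUE, c("theta4", "theta5"),
      variance_fn = function(ipred, p) ipred^2 * p_get(p, "theta4")^2 + p_get(p, "theta5")^2,
      w_fn = function(ipred, p) sqrt(ipred^2 * p_get(p, "theta4")^2 + p_get(p, "theta5")^2),
      dvar_fn = function(ipred, p) 2 * ipred * p_get(p, "theta4")^2,
      y_label = "Y = IPRED + W*ERR(1)",
      w_label = "W = SQRT(IPRED**2 * THETA(4)**2 + THETA(5)**2)"
    ),
    COMB_SD = new_coding("COMB_SD", "combined", "theta", 1, TRUE, c("theta4", "theta5"),
      variance_fn = function(ipred, p) (p_get(p, "theta4") * ipred + p_get(p, "theta5"))^2,
      w_fn = function(ipred, p) p_get(p, "theta4") * ipred + p_get(p, "theta5"),
      dvar_fn = function(ipred, p) {
        2 * p_get(p, "theta4") * (p_get(p, "theta4") * ipred + p_get(p, "theta5"))
      },
      y_label = "Y = IPRED + W*ERR(1)", w_label = "W = THETA(4)*IPRED + THETA(5)"
    )
  )
}

#' Look up a single error coding by id
#'
#' @param id One of `"ADD.1"`, `"ADD.2"`, `"ADD.3"`, `"PROP.1"`, `"PROP.2"`,
#'   `"PROP.3"`, `"COMB_VAR1"`, `"COMB_VAR3"`, `"COMB_SD"`.
#' @return An `error_coding` object.
#' @export
error_coding <- function(id) {
  reg <- error_codings()
  if (!id %in% names(reg)) {
    abort(paste0(
      "unknown error coding `", id, "`; available: ",
      paste(names(reg), collapse = ", ")
    ), class = "ruvdiag_configuration_error")
  }
  reg[[id]]
}

#' Evaluate the diagnostic scale W of a coding
#'
#' @param coding An [error_coding()] object.
#' @param ipred Individual predicted concentration(s) (mg/L).
#' @param params An [err_params()] object with the slots the coding uses.
#' @return W (mg/L), same length as `ipred`.
#' @examples
#' w_value(error_coding("ADD.1"), 1, err_params(sigma1 = 0.216))
#' @export
w_value <- function(coding, ipred, params) {
  stopifnot(inherits(coding, "error_coding"))
  coding$w_fn(ipred, params)
}

#' Evaluate the likelihood residual variance of a coding
#'
#' The variance implied by the observation equation Y, i.e. the quantity that
#' enters the likelihood; independent of the diagnostic scale W.
#'
#' @inheritParams w_value
#' @return Residual variance ((mg/L)^2), same length as `ipred`.
#' @examples
#' variance_value(error_coding("COMB_SD"), 2, err_params(theta4 = 0.15, theta5 = 0.5))
#' @export
variance_value <- function(coding, ipred, params) {
  stopifnot(inherits(coding, "error_coding"))
  coding$variance_fn(ipred, params)
}

#' @export
print.error_coding <- function(x, ...) {
  cat("<error_coding> ", x$id, " (", x$error_type, ", ", x$param_style, "-based",
    if (x$fixed_sigma) ", $SIGMA 1 FIX" else "", ")\n",
    sep = ""
  )
  cat("  ", x$y_label, "\n  ", x$w_label, "\n", sep = "")
  invisible(x)
}
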