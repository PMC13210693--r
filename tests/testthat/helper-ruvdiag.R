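# Shared helpers for the test suite.

# Small simulated dataset with the study defaults except size/seed.
toy_dataset <- function(kind = "additive", n = 20, seed = 42, ...) {
  suppressMessages(simulate_dataset(sim_protocol(kind, n_subjects = n, seed = seed, ...)))
}

# Default truth parameter point for a protocol, expressed for a given coding.
truth_params <- function(protocol, coding_id) {
  coding <- error_coding(coding_id)
  err <- switch(coding_id,
    ADD.1 = ,
    ADD.2 = err_params(sigma1 = protocol$sigma_add^2),
    ADD.3 = err_params(theta4 = protocol$sigma_add),
    PROP.1 = ,
    PROP.2 = err_params(sigma1 = protocol$sigma_prop^2),
    PROP.3 = err_params(theta4 = protocol$sigma_prop),
    COMB_VAR1 = err_params(
      sigma1 = protocol$sigma_prop^2, sigma2 = protocol$sigma_add^2
    ),
    COMB_VAR3 = ,
    COMB_SD = err_params(theta4 = protocol$sigma_prop, theta5 = protocol$sigma_add)
  )
  pop_params(
    tvcl = protocol$structural[["tvcl"]], tvv = protocol$structural[["tvv"]],
    ka = protocol$structural[["ka"]],
    omega2_cl = protocol$omega2_cl, omega2_v = protocol$omega2_v, err = err
  )
}

# Central finite-difference gradient of a scalar function.
num_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# Random-intercept linear model spec for oracle tests: f = mu + eta, one eta.
intercept_model <- function() {
  ruvdiag:::model_spec(
    n_eta = 1,
    predict = function(struct, eta_rows, time, amt) {
      struct[["tvcl"]] + eta_rows[, 1]
    },
    jacobian = function(struct, eta_rows, time, amt) {
      matrix(1, length(time), 1)
    },
    eta_names = "eta_1"
  )
}

# Exact -2 log likelihood (without the n log 2pi constant) of the
# random-intercept Gaussian model y_i ~ N(mu, sigma2 I + omega2 11').
lmm_m2ll <- function(data, mu, omega2, sigma2) {
  obs <- data[data$EVID == 0, ]
  out <- 0
  for (id in unique(obs$ID)) {
    y <- obs$DV[obs$ID == id]
    n <- length(y)
    v <- diag(sigma2, n) + matrix(omega2, n, n)
    r <- y - mu
    out <- out + determinant(v, logarithm = TRUE)$modulus[1] +
      drop(r %*% solve(v, r))
  }
  out
}
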