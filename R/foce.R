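# First-order conditional estimation with interaction (FOCE-I).
#
# Inner problem: per-subject MAP (empirical Bayes) eta, minimizing
#   sum_j [ log v_j(eta) + (y_j - f_j(eta))^2 / v_j(eta) ] + eta' Omega^-1 eta
# with the residual variance v evaluated at the conditional prediction
# (the interaction). Solved by a damped Gauss-Newton iteration, vectorized
# across subjects.
#
# Outer problem: the FOCE-I objective (-2 log marginal likelihood without the
# n log 2pi constant),
#   OFV = sum_i [ log|V_i| + r_i' V_i^-1 r_i ]
#   V_i = J_i Omega J_i' + diag(v_ij(etahat_i)),  r_i = y_i - f_i(etahat_i) + J_i etahat_i
# minimized by BFGS over log-transformed parameters, followed by Newton
# polishing steps on a finite-difference gradient/Hessian.

#' Population parameter set
#'
#' Bundles the structural parameters, the between-subject variances (diagonal
#' Omega, log scale) and the residual-error parameters of a coding.
#'
#' @param tvcl,tvv Typical apparent clearance (L/h) and volume (L).
#' @param ka Absorption rate constant (1/h); fixed during estimation.
#' @param omega2_cl,omega2_v Between-subject variances on log CL and log V.
#' @param err An [err_params()] object.
#' @return A `pop_params` object.
#' @examples
#' pop_params(5, 50, omega2_cl = 0.09, omega2_v = 0.09, err = err_params(sigma1 = 0.25))
#' @export
pop_params <- function(tvcl, tvv, ka = 1.0, omega2_cl, omega2_v, err) {
  check_pos(c(tvcl, tvv, ka), "tvcl/tvv/ka")
  stopifnot(omega2_cl >= 0, omega2_v >= 0, inherits(err, "err_params"))
  structure(
    list(
      struct = c(tvcl = tvcl, tvv = tvv, ka = ka),
      omega2 = c(cl = omega2_cl, v = omega2_v),
      err = err
    ),
    class = "pop_params"
  )
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params> TVCL", x$struct[["tvcl"]], "L/h, TVV", x$struct[["tvv"]],
    "L, KA", x$struct[["ka"]], "/h\n  omega2:", x$omega2[["cl"]], x$omega2[["v"]], "\n"
  )
  act <- names(which(!vapply(unclass(x$err), is.null, logical(1))))
  cat("  err:", paste(act, unlist(x$err[act]), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- data preparation --------------------------------------------------------

prep_nm <- function(data) {
  missing <- setdiff(nm_required_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing required column(s): ", paste(missing, collapse = ", ")),
      class = "ruvdiag_format_error"
    )
  }
  obs <- data[data$MDV == 0 & data$EVID == 0, ]
  if (nrow(obs) == 0) abort("dataset has no observation rows", class = "ruvdiag_format_error")
  ids <- unique(data$ID)
  doses <- data[data$EVID == 1, c("ID", "AMT")]
  dose_by_id <- doses$AMT[match(ids, doses$ID)]
  if (any(is.na(dose_by_id))) {
    abort("every subject needs a dose record (EVID = 1 with AMT > 0)",
      class = "ruvdiag_format_error"
    )
  }
  subj <- match(obs$ID, ids)
  # subject-contiguous ordering so that rowsum() groups line up with 1..n
  o <- order(subj, obs$TIME)
  obs <- obs[o, ]
  subj <- subj[o]
  list(
    ids = ids, n_sub = length(ids), n_obs = nrow(obs),
    subj = subj, time = obs$TIME, y = obs$DV, amt = dose_by_id[subj],
    obs = obs
  )
}

# ---- inner problem -----------------------------------------------------------

# Per-subject MAP objective contributions (without log|Omega|), vectorized.
inner_q <- function(eta, prep, model, struct, omega2, coding, ep) {
  er <- eta[prep$subj, , drop = FALSE]
  f <- model$predict(struct, er, prep$time, prep$amt)
  v <- coding$variance_fn(f, ep)
  r <- prep$y - f
  contrib <- rep(Inf, length(v))
  ok <- is.finite(v) & v > 0
  contrib[ok] <- log(v[ok]) + r[ok]^2 / v[ok]
  drop(rowsum(contrib, prep$subj, reorder = FALSE)) +
    as.vector((eta^2) %*% (1 / omega2))
}

inner_newton <- function(prep, model, struct, omega2, coding, ep,
                         eta0 = NULL, tol = 1e-8, maxit = 100L) {
  k <- model$n_eta
  n <- prep$n_sub
  if (all(omega2 <= 0)) {
    return(list(
      eta = matrix(0, n, k), converged = rep(TRUE, n),
      iterations = 0L, max_grad = 0
    ))
  }
  if (any(omega2 <= 0)) {
    abort("mixed zero/positive omega2 is not supported; fix the zero variance out of the model",
      class = "ruvdiag_configuration_error"
    )
  }
  oinv <- 1 / omega2
  subj <- prep$subj
  eta <- if (is.null(eta0)) matrix(0, n, k) else eta0
  qi <- inner_q(eta, prep, model, struct, omega2, coding, ep)
  if (!is.null(eta0)) {
    # start each subject from the better of the warm start and the prior mode,
    # so a warm start carried over from an extreme parameter point cannot
    # strand the solver in a bad basin
    qi0 <- inner_q(matrix(0, n, k), prep, model, struct, omega2, coding, ep)
    use0 <- !is.finite(qi) | qi0 < qi
    if (any(use0)) {
      eta[use0, ] <- 0
      qi[use0] <- qi0[use0]
    }
  } else if (any(!is.finite(qi))) {
    eta[!is.finite(qi), ] <- 0
    qi <- inner_q(eta, prep, model, struct, omega2, coding, ep)
  }
  gmax <- rep(Inf, n)
  workmask <- rep(TRUE, n)
  it <- 0L
  for (it in seq_len(maxit)) {
    work <- which(workmask)
    if (length(work) == 0) break
    rows <- which(workmask[subj])
    grp <- match(subj[rows], work)
    tw <- prep$time[rows]
    aw <- prep$amt[rows]
    yw <- prep$y[rows]
    eta_w <- eta[work, , drop = FALSE]
    qi_w <- qi[work]

    q_w <- function(em) {
      er <- em[grp, , drop = FALSE]
      f <- model$predict(struct, er, tw, aw)
      v <- coding$variance_fn(f, ep)
      r <- yw - f
      contrib <- rep(Inf, length(v))
      ok <- is.finite(v) & v > 0
      contrib[ok] <- log(v[ok]) + r[ok]^2 / v[ok]
      drop(rowsum(contrib, grp, reorder = FALSE)) + as.vector((em^2) %*% oinv)
    }

    er <- eta_w[grp, , drop = FALSE]
    f <- model$predict(struct, er, tw, aw)
    jac <- model$jacobian(struct, er, tw, aw)
    v <- coding$variance_fn(f, ep)
    dv <- coding$dvar_fn(f, ep)
    r <- yw - f
    coef <- dv / v - 2 * r / v - r^2 * dv / v^2
    grad <- rowsum(jac * coef, grp, reorder = FALSE) +
      2 * sweep(eta_w, 2, oinv, `*`)
    gm <- apply(abs(grad), 1, max)
    gm[!is.finite(gm)] <- Inf
    grad[!is.finite(grad)] <- 0
    gmax[work] <- gm
    done <- gm <= tol
    if (all(done)) {
      workmask[work] <- FALSE
      break
    }
    # Fisher-scoring Hessian of the MAP objective (SPD): per-observation
    # weight 2/v from the mean model plus (v'/v)^2 from the variance model
    wrow <- 2 / v + (dv / v)^2
    if (k == 1) {
      h11 <- drop(rowsum(jac[, 1]^2 * wrow, grp, reorder = FALSE)) + 2 * oinv[1]
      delta <- grad / h11
    } else {
      h11 <- drop(rowsum(jac[, 1]^2 * wrow, grp, reorder = FALSE)) + 2 * oinv[1]
      h22 <- drop(rowsum(jac[, 2]^2 * wrow, grp, reorder = FALSE)) + 2 * oinv[2]
      h12 <- drop(rowsum(jac[, 1] * jac[, 2] * wrow, grp, reorder = FALSE))
      det <- h11 * h22 - h12^2
      ridge <- !is.finite(det) | det <= 1e-12 * h11 * h22
      ridge[is.na(ridge)] <- TRUE
      if (any(ridge)) {
        h11[ridge] <- h11[ridge] * 1.01 + 1e-8
        h22[ridge] <- h22[ridge] * 1.01 + 1e-8
        det <- h11 * h22 - h12^2
      }
      delta <- cbind(
        (h22 * grad[, 1] - h12 * grad[, 2]) / det,
        (h11 * grad[, 2] - h12 * grad[, 1]) / det
      )
    }
    delta[!is.finite(delta)] <- 0
    delta[done, ] <- 0
    # two-point line search (full and half Newton step), then backtracking;
    # the half step damps the oscillation a Fisher direction can produce when
    # the true curvature exceeds the scoring approximation
    q1 <- q_w(eta_w - delta)
    q2 <- q_w(eta_w - 0.5 * delta)
    use2 <- q2 < q1
    delta[use2, ] <- 0.5 * delta[use2, , drop = FALSE]
    qn <- pmin(q1, q2)
    trial <- eta_w - delta
    for (h in seq_len(20)) {
      bad <- !done & !(qn <= qi_w + 1e-12)
      if (!any(bad)) break
      delta[bad, ] <- delta[bad, ] / 2
      trial[bad, ] <- eta_w[bad, , drop = FALSE] - delta[bad, , drop = FALSE]
      qt <- q_w(trial)
      qn[bad] <- qt[bad]
    }
    stuck <- !done & !(qn <= qi_w + 1e-12)
    trial[stuck, ] <- eta_w[stuck, , drop = FALSE]
    qn[stuck] <- qi_w[stuck]
    eta[work, ] <- trial
    qi[work] <- qn
    # freeze converged subjects and those where no improving step exists
    workmask[work[done | stuck]] <- FALSE
  }
  colnames(eta) <- model$eta_names
  list(eta = eta, converged = gmax <= tol * 10, iterations = it, max_grad = max(gmax))
}

# ---- FOCE objective ----------------------------------------------------------

# OFV and per-subject pieces at given etahat. Returns ok = FALSE with the id of
# the first offending subject if any marginal covariance is not positive
# definite or a residual variance is invalid.
ofv_core <- function(prep, model, struct, omega2, coding, ep, eta) {
  k <- model$n_eta
  if (all(omega2 <= 0)) {
    er <- matrix(0, prep$n_obs, k)
    f <- model$predict(struct, er, prep$time, prep$amt)
    v <- coding$variance_fn(f, ep)
    if (any(!is.finite(v) | v <= 0)) {
      return(list(ok = FALSE, bad = prep$ids[prep$subj[which(!is.finite(v) | v <= 0)[1]]]))
    }
    r <- prep$y - f
    return(list(ok = TRUE, ofv = sum(log(v) + r^2 / v)))
  }
  er <- eta[prep$subj, , drop = FALSE]
  f <- model$predict(struct, er, prep$time, prep$amt)
  jac <- model$jacobian(struct, er, prep$time, prep$amt)
  v <- coding$variance_fn(f, ep)
  if (any(!is.finite(v) | v <= 0)) {
    return(list(ok = FALSE, bad = prep$ids[prep$subj[which(!is.finite(v) | v <= 0)[1]]]))
  }
  r <- prep$y - f + rowSums(jac * eta[prep$subj, , drop = FALSE])
  g <- prep$subj
  sl <- drop(rowsum(log(v), g, reorder = FALSE))
  s0 <- drop(rowsum(r^2 / v, g, reorder = FALSE))
  oinv <- 1 / omega2
  if (k == 1) {
    a11 <- drop(rowsum(jac[, 1]^2 / v, g, reorder = FALSE))
    b1 <- drop(rowsum(jac[, 1] * r / v, g, reorder = FALSE))
    m <- oinv[1] + a11
    bad <- !is.finite(m) | m <= 0
    if (any(bad)) return(list(ok = FALSE, bad = prep$ids[which(bad)[1]]))
    ofv_i <- sl + log(omega2[1]) + log(m) + s0 - b1^2 / m
  } else {
    a11 <- drop(rowsum(jac[, 1]^2 / v, g, reorder = FALSE))
    a22 <- drop(rowsum(jac[, 2]^2 / v, g, reorder = FALSE))
    a12 <- drop(rowsum(jac[, 1] * jac[, 2] / v, g, reorder = FALSE))
    b1 <- drop(rowsum(jac[, 1] * r / v, g, reorder = FALSE))
    b2 <- drop(rowsum(jac[, 2] * r / v, g, reorder = FALSE))
    m11 <- oinv[1] + a11
    m22 <- oinv[2] + a22
    det <- m11 * m22 - a12^2
    bad <- !is.finite(det) | det <= 0
    if (any(bad)) return(list(ok = FALSE, bad = prep$ids[which(bad)[1]]))
    quad <- s0 - (m22 * b1^2 - 2 * a12 * b1 * b2 + m11 * b2^2) / det
    ofv_i <- sl + sum(log(omega2)) + log(det) + quad
  }
  list(ok = TRUE, ofv = sum(ofv_i), ofv_i = ofv_i)
}

#' MAP objective for one subject
#'
#' The conditional (inner) objective minimized by the empirical Bayes eta
#' estimate: `sum_j [log v_j + (y_j - f_j)^2 / v_j] + eta' Omega^-1 eta +
#' log|Omega|`, with the residual variance evaluated at the conditional
#' prediction (interaction).
#'
#' @param data Dataset rows for a single subject (dose + observation records).
#' @param eta Length-2 numeric vector of random effects.
#' @param pop A [pop_params()] object.
#' @param coding An [error_coding()] object.
#' @return Scalar objective value.
#' @export
map_objective <- function(data, eta, pop, coding) {
  prep <- prep_nm(data)
  if (prep$n_sub != 1) abort("`map_objective()` expects a single subject", class = "ruvdiag_configuration_error")
  model <- pk_model_spec()
  omega2 <- unname(pop$omega2)
  if (any(omega2 <= 0)) abort("Omega must be invertible", class = "ruvdiag_numerical_error")
  q <- inner_q(matrix(eta, 1), prep, model, pop$struct, omega2, coding, pop$err)
  if (!is.finite(q)) {
    abort("residual variance non-positive at some observation for this eta",
      class = "ruvdiag_numerical_error"
    )
  }
  unname(q) + sum(log(omega2))
}

#' Empirical Bayes (MAP) eta estimates
#'
#' Minimizes the per-subject MAP objective for every subject, starting from
#' `eta = 0` with fixed tolerances, so the result is deterministic given the
#' inputs.
#'
#' @inheritParams map_objective
#' @param data Dataset tibble (`ID, TIME, AMT, DV, EVID, MDV`).
#' @return Tibble with one row per subject: `ID`, `eta_cl`, `eta_v`, and
#'   `converged` (inner gradient norm below tolerance).
#' @export
estimate_etas <- function(data, pop, coding) {
  prep <- prep_nm(data)
  model <- pk_model_spec()
  fit <- inner_newton(prep, model, pop$struct, unname(pop$omega2), coding, pop$err)
  if (!all(fit$converged)) {
    warn(paste0(
      "inner eta optimization did not reach tolerance for ",
      sum(!fit$converged), " subject(s)"
    ))
  }
  tibble::tibble(
    ID = prep$ids,
    eta_cl = fit$eta[, 1], eta_v = fit$eta[, 2],
    converged = fit$converged
  )
}

#' FOCE-I objective function value
#'
#' Computes the FOCE-I approximation to -2 log marginal likelihood (excluding
#' the additive constant `n log 2pi`, following the usual OFV convention) at a
#' given population parameter point: empirical Bayes etas are estimated
#' internally, the model is linearized at them, and the per-subject marginal
#' covariance `V_i = J_i Omega J_i' + diag(v_ij)` is assembled with the
#' residual variance evaluated at the conditional predictions (interaction).
#'
#' @inheritParams estimate_etas
#' @param model Internal model spec; defaults to the one-compartment oral
#'   model. Exposed so that linear test models can be swapped in.
#' @return Scalar OFV.
#' @export
foce_ofv <- function(data, pop, coding, model = pk_model_spec()) {
  prep <- prep_nm(data)
  omega2 <- unname(pop$omega2)[seq_len(model$n_eta)]
  inner <- inner_newton(prep, model, pop$struct, omega2, coding, pop$err)
  res <- ofv_core(prep, model, pop$struct, omega2, coding, pop$err, inner$eta)
  if (!res$ok) {
    abort(paste0("marginal covariance not positive definite (subject ", res$bad, ")"),
      class = "ruvdiag_numerical_error"
    )
  }
  res$ofv
}

# ---- outer problem -----------------------------------------------------------

fd_grad <- function(fn, x, h) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h[i]
    (fn(x + e) - fn(x - e)) / (2 * h[i])
  }, numeric(1))
}

fd_hessian <- function(fn, x, h) {
  p <- length(x)
  hess <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- numeric(p)
    ei[i] <- h[i]
    hess[i, i] <- (fn(x + 2 * ei) - 2 * f0 + fn(x - 2 * ei)) / (4 * h[i]^2)
    for (j in seq_len(p)) {
      if (j <= i) next
      ej <- numeric(p)
      ej[j] <- h[j]
      hess[i, j] <- hess[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
          (4 * h[i] * h[j])
    }
  }
  hess
}

#' Fit a population PK model by FOCE-I
#'
#' Estimates the typical clearance and volume, the two between-subject
#' variances and the residual-error parameters of the chosen coding by
#' minimizing the FOCE-I objective. KA is fixed (at its value in `init`).
#' All parameters are log-transformed internally to enforce positivity;
#' estimates are reported back on the conventional scales (SIGMA entries as
#' variances, THETA entries as standard deviations). BFGS minimization is
#' followed by Newton polishing steps on a finite-difference gradient and
#' Hessian, from which standard errors are also derived (delta method on the
#' log scale).
#'
#' @inheritParams estimate_etas
#' @param init A [pop_params()] object of initial estimates; its `err` slot
#'   must populate the parameter slots used by `coding`.
#' @param control Optional list overriding `inner_tol` (1e-8), `inner_maxit`
#'   (100), `reltol` (1e-10), `maxit` (500), `polish` (2), `se` (TRUE).
#' @return A `foce_fit` object: estimated [pop_params()], `ofv`, per-subject
#'   empirical Bayes etas, convergence metadata, standard errors, the
#'   log-scale covariance matrix and the data fitted. Methods: [tidy()],
#'   [glance()], [augment()], `print()`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(sim_protocol("additive", n_subjects = 40, seed = 7))
#' init <- pop_params(6, 60, omega2_cl = 0.1, omega2_v = 0.1, err = err_params(sigma1 = 0.3))
#' fit <- foce_fit(ds, error_coding("ADD.1"), init)
#' glance(fit)
#' }
#' @export
foce_fit <- function(data, coding, init, control = list()) {
  stopifnot(inherits(coding, "error_coding"), inherits(init, "pop_params"))
  ctrl <- utils::modifyList(
    list(
      inner_tol = 1e-8, inner_maxit = 100L, reltol = 1e-10, maxit = 500L,
      polish = 2L, se = TRUE
    ),
    control
  )
  model <- pk_model_spec()
  prep <- prep_nm(data)

  terms <- c("tvcl", "tvv", "omega2_cl", "omega2_v", coding$active)
  par0 <- log(c(
    init$struct[["tvcl"]], init$struct[["tvv"]],
    init$omega2[["cl"]], init$omega2[["v"]],
    vapply(coding$active, function(nm) p_get(init$err, nm), numeric(1))
  ))
  names(par0) <- terms
  ka <- init$struct[["ka"]]

  unpack <- function(par) {
    e <- exp(par)
    list(
      struct = c(tvcl = e[[1]], tvv = e[[2]], ka = ka),
      omega2 = c(e[[3]], e[[4]]),
      ep = do.call(err_params, as.list(setNames(e[-(1:4)], coding$active)))
    )
  }

  cache <- new.env(parent = emptyenv())
  cache$eta <- matrix(0, prep$n_sub, model$n_eta)
  cache$failures <- 0L
  cache$evals <- 0L

  ofv_at <- function(par, update_cache = TRUE) {
    # keep BFGS trial points inside a numerically safe box on the log scale
    if (any(!is.finite(par)) || any(abs(par) > 20)) {
      return(1e10 + sum(pmin(abs(par[is.finite(par)]), 1e3)))
    }
    u <- unpack(par)
    solve_from <- function(eta0) {
      inner <- inner_newton(prep, model, u$struct, u$omega2, coding, u$ep,
        eta0 = eta0, tol = ctrl$inner_tol, maxit = ctrl$inner_maxit
      )
      list(inner = inner, res = ofv_core(prep, model, u$struct, u$omega2, coding, u$ep, inner$eta))
    }
    s <- solve_from(cache$eta)
    if (!s$res$ok || !is.finite(s$res$ofv)) {
      # the warm start can be unusable after an extreme trial point; retry cold
      s <- solve_from(matrix(0, prep$n_sub, model$n_eta))
    }
    if (update_cache) {
      cache$evals <- cache$evals + 1L
      if (!all(s$inner$converged)) cache$failures <- cache$failures + 1L
    }
    if (!s$res$ok || !is.finite(s$res$ofv)) {
      return(1e10)
    }
    # cache only successful solves so one bad point cannot poison later ones
    if (update_cache) cache$eta <- s$inner$eta
    s$res$ofv
  }

  opt <- optim(par0, ofv_at,
    method = "BFGS",
    control = list(
      reltol = ctrl$reltol, maxit = ctrl$maxit,
      ndeps = rep(1e-5, length(par0))
    )
  )
  par <- opt$par
  ofv <- opt$value

  # Newton polish on a frozen eta warm-start cache (deterministic function of par)
  frozen <- function(par) ofv_at(par, update_cache = FALSE)
  hstep <- rep(1e-4, length(par))
  hess <- NULL
  gstep <- rep(1e-5, length(par)) # below this, inner-solve noise dominates the FD quotient
  i <- 0L
  for (i in seq_len(ctrl$polish)) {
    gr <- fd_grad(frozen, par, gstep)
    hess <- fd_hessian(frozen, par, hstep)
    step <- tryCatch(solve(hess, gr), error = function(e) gr * 0)
    cand <- par - step
    val <- ofv_at(cand)
    if (is.finite(val) && val <= ofv + 1e-6) {
      par <- cand
      ofv <- min(val, ofv)
    } else {
      break
    }
  }
  grad_final <- fd_grad(frozen, par, gstep)
  if (is.null(hess) || any(!is.finite(hess))) hess <- fd_hessian(frozen, par, hstep)

  est <- exp(par)
  se_log <- rep(NA_real_, length(par))
  vcov_log <- NULL
  if (ctrl$se) {
    vcov_log <- tryCatch(
      {
        v <- solve(hess / 2)
        if (any(diag(v) <= 0)) stop("indefinite")
        v
      },
      error = function(e) {
        warn("Hessian not positive definite at the optimum; standard errors omitted")
        NULL
      }
    )
    if (!is.null(vcov_log)) se_log <- sqrt(diag(vcov_log))
  }
  se <- est * se_log # delta method: se of exp(x)

  u <- unpack(par)
  inner <- inner_newton(prep, model, u$struct, u$omega2, coding, u$ep,
    eta0 = cache$eta, tol = ctrl$inner_tol, maxit = ctrl$inner_maxit
  )
  params <- pop_params(
    tvcl = est[[1]], tvv = est[[2]], ka = ka,
    omega2_cl = est[[3]], omega2_v = est[[4]], err = u$ep
  )
  converged <- opt$convergence == 0 && max(abs(grad_final)) < 0.1
  if (!converged) {
    warn(paste0(
      "fit for coding ", coding$id, " may not have converged (optim code ",
      opt$convergence, ", |grad| ", format(max(abs(grad_final)), digits = 3), ")"
    ))
  }
  structure(
    list(
      params = params, ofv = ofv, coding = coding,
      etas = tibble::tibble(
        ID = prep$ids,
        eta_cl = inner$eta[, 1], eta_v = inner$eta[, 2]
      ),
      terms = terms, estimates = setNames(est, terms), se = setNames(se, terms),
      vcov_log = vcov_log, par_log = par,
      convergence = list(
        success = converged, optim_code = opt$convergence,
        ofv_evals = cache$evals, grad_norm = max(abs(grad_final)),
        inner_failures = cache$failures, polish_steps = i
      ),
      n_subjects = prep$n_sub, n_obs = prep$n_obs,
      data = data, init = init
    ),
    class = "foce_fit"
  )
}

#' @export
print.foce_fit <- function(x, ...) {
  cat("<foce_fit> coding ", x$coding$id, "  OFV ", format(x$ofv, nsmall = 2),
    "  (", x$n_subjects, " subjects, ", x$n_obs, " obs)\n",
    sep = ""
  )
  print(tidy_foce(x), n = Inf)
  invisible(x)
}

#' Standard errors of a converged fit
#'
#' @param fit A `foce_fit` object.
#' @return Named numeric vector of standard errors on the reporting scale
#'   (delta method from the log-scale covariance); `NA` where unavailable.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "foce_fit"))
  fit$se
}
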