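# FOCE-I engine: inner MAP problem, objective, estimation, accessors.

test_that("map_objective reproduces its definition at eta = 0", {
  ds <- toy_dataset("additive", n = 1, seed = 5)
  pop <- truth_params(attr(ds, "protocol"), "ADD.1")
  obs <- ds[ds$EVID == 0, ]
  f <- pk_conc(obs$TIME, 100, 5, 50, 1)
  v <- 0.25 # sigma_add^2
  by_hand <- sum(log(v) + (obs$DV - f)^2 / v) + log(0.09) + log(0.09)
  expect_equal(map_objective(ds, c(0, 0), pop, error_coding("ADD.1")), by_hand,
    tolerance = 1e-12
  )
  # the eta prior term: quadratic penalty with the Omega inverse
  eta <- c(0.2, -0.1)
  expect_equal(
    map_objective(ds, eta, pop, error_coding("ADD.2")) -
      map_objective(ds, c(0, 0), pop, error_coding("ADD.2")),
    sum(log(v) + (obs$DV - pk_conc(obs$TIME, 100, 5 * exp(0.2), 50 * exp(-0.1), 1))^2 / v) -
      sum(log(v) + (obs$DV - f)^2 / v) + sum(eta^2 / 0.09),
    tolerance = 1e-10
  )
})

test_that("empirical Bayes etas are stationary points of the MAP objective", {
  for (kind_coding in list(
    c("additive", "ADD.1"), c("proportional", "PROP.1"),
    c("combined", "COMB_SD")
  )) {
    ds <- toy_dataset(kind_coding[1], n = 8, seed = 21)
    pop <- truth_params(attr(ds, "protocol"), kind_coding[2])
    coding <- error_coding(kind_coding[2])
    et <- estimate_etas(ds, pop, coding)
    expect_true(all(et$converged))
    for (id in c(1, 5, 8)) {
      sub <- ds[ds$ID == id, ]
      g <- num_grad(
        function(e) map_objective(sub, e, pop, coding),
        c(et$eta_cl[id], et$eta_v[id]),
        h = 1e-5
      )
      expect_lt(max(abs(g)), 1e-4)
    }
  }
})

test_that("etas are recovered on nearly noise-free data", {
  ds <- toy_dataset("additive", n = 25, seed = 31, sigma_add = 1e-4)
  pop <- truth_params(attr(ds, "protocol"), "ADD.1")
  pop$err <- err_params(sigma1 = 1e-8)
  # with a near-zero residual variance the inner gradient scale is ~1/sigma1,
  # so the absolute tolerance is not reachable for every subject; the etas are
  # still recovered, which is what this test asserts
  et <- suppressWarnings(estimate_etas(ds, pop, error_coding("ADD.1")))
  eta_true <- attr(ds, "eta")
  expect_equal(et$eta_cl, unname(eta_true[, 1]), tolerance = 1e-2)
  expect_equal(et$eta_v, unname(eta_true[, 2]), tolerance = 1e-2)
})

test_that("the OFV ignores W: shared-variance codings give identical values", {
  ds <- toy_dataset("additive", n = 15, seed = 8)
  proto <- attr(ds, "protocol")
  o1 <- foce_ofv(ds, truth_params(proto, "ADD.1"), error_coding("ADD.1"))
  o2 <- foce_ofv(ds, truth_params(proto, "ADD.2"), error_coding("ADD.2"))
  o3 <- foce_ofv(ds, truth_params(proto, "ADD.3"), error_coding("ADD.3"))
  expect_identical(o1, o2)
  expect_equal(o1, o3, tolerance = 1e-12)
  dsp <- toy_dataset("proportional", n = 15, seed = 8)
  protop <- attr(dsp, "protocol")
  p1 <- foce_ofv(dsp, truth_params(protop, "PROP.1"), error_coding("PROP.1"))
  p2 <- foce_ofv(dsp, truth_params(protop, "PROP.2"), error_coding("PROP.2"))
  expect_identical(p1, p2)
})

test_that("FOCE OFV equals the closed-form linear mixed model -2LL", {
  # random-intercept Gaussian model: the linearization is exact, so the
  # FOCE objective must match the marginal likelihood to numerical precision
  set.seed(404)
  n <- 12
  nt <- 6
  mu <- 2.5
  omega2 <- 0.4
  sigma2 <- 0.09
  b <- rnorm(n, 0, sqrt(omega2))
  obs <- tibble::tibble(
    ID = rep(seq_len(n), each = nt),
    TIME = rep(seq_len(nt), n),
    AMT = NA_real_,
    DV = mu + b[rep(seq_len(n), each = nt)] + rnorm(n * nt, 0, sqrt(sigma2)),
    EVID = 0L, MDV = 0L
  )
  dose <- tibble::tibble(
    ID = seq_len(n), TIME = 0, AMT = 1, DV = NA_real_, EVID = 1L, MDV = 1L
  )
  ds <- rbind(dose, obs)
  pop <- pop_params(
    tvcl = mu, tvv = 1, ka = 1,
    omega2_cl = omega2, omega2_v = 1, err = err_params(sigma1 = sigma2)
  )
  ofv <- foce_ofv(ds, pop, error_coding("ADD.2"), model = intercept_model())
  expect_equal(ofv, lmm_m2ll(ds, mu, omega2, sigma2), tolerance = 1e-8)
})

test_that("with Omega = 0 the OFV is the exact heteroscedastic -2LL", {
  ds <- toy_dataset("proportional", n = 10, seed = 77)
  pop <- pop_params(5, 50,
    ka = 1, omega2_cl = 0, omega2_v = 0,
    err = err_params(sigma1 = 0.04)
  )
  obs <- ds[ds$EVID == 0, ]
  f <- pk_conc(obs$TIME, 100, 5, 50, 1)
  v <- f^2 * 0.04
  expect_equal(
    foce_ofv(ds, pop, error_coding("PROP.1")),
    sum(log(v) + (obs$DV - f)^2 / v),
    tolerance = 1e-10
  )
  # and the positive-Omega objective approaches it as Omega -> 0
  pop_eps <- pop_params(5, 50,
    ka = 1, omega2_cl = 1e-12, omega2_v = 1e-12,
    err = err_params(sigma1 = 0.04)
  )
  expect_equal(
    foce_ofv(ds, pop_eps, error_coding("PROP.1")),
    foce_ofv(ds, pop, error_coding("PROP.1")),
    tolerance = 1e-4
  )
})

test_that("foce_fit estimates a small additive dataset sensibly", {
  ds <- toy_dataset("additive", n = 60, seed = 19)
  init <- pop_params(6, 60,
    ka = 1, omega2_cl = 0.12, omega2_v = 0.12,
    err = err_params(sigma1 = 0.4)
  )
  fit <- foce_fit(ds, error_coding("ADD.1"), init)
  expect_s3_class(fit, "foce_fit")
  expect_true(fit$convergence$success)
  expect_identical(fit$terms, c("tvcl", "tvv", "omega2_cl", "omega2_v", "sigma1"))
  # loose recovery bounds appropriate for 60 subjects
  expect_equal(unname(fit$estimates[["tvcl"]]), 5, tolerance = 0.15)
  expect_equal(unname(fit$estimates[["tvv"]]), 50, tolerance = 0.15)
  expect_equal(unname(fit$estimates[["sigma1"]]), 0.25, tolerance = 0.35)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  expect_identical(standard_errors(fit), fit$se)

  # the fitted OFV is a minimum along each coordinate
  pert <- fit$params
  pert$struct[["tvcl"]] <- pert$struct[["tvcl"]] * 1.05
  expect_gt(foce_ofv(ds, pert, error_coding("ADD.1")), fit$ofv)

  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, fit$terms)
  expect_equal(td$estimate, unname(fit$estimates))
  gl <- glance(fit)
  expect_equal(gl$ofv, fit$ofv)
  expect_equal(gl$n_obs, 720)
  expect_equal(gl$ruv_sd, sqrt(fit$estimates[["sigma1"]]), ignore_attr = TRUE)
  au <- augment(fit)
  expect_s3_class(au, "nm_diag")
  expect_equal(nrow(au), 720)
})

test_that("fits of reparameterized codings land on the same optimum", {
  ds <- toy_dataset("additive", n = 40, seed = 23)
  init1 <- pop_params(6, 60,
    ka = 1, omega2_cl = 0.12, omega2_v = 0.12,
    err = err_params(sigma1 = 0.36)
  )
  init3 <- pop_params(6, 60,
    ka = 1, omega2_cl = 0.12, omega2_v = 0.12,
    err = err_params(theta4 = 0.6)
  )
  f1 <- foce_fit(ds, error_coding("ADD.1"), init1)
  f3 <- foce_fit(ds, error_coding("ADD.3"), init3)
  expect_equal(f1$ofv, f3$ofv, tolerance = 1e-6)
  expect_equal(f1$estimates[["tvcl"]], f3$estimates[["tvcl"]], tolerance = 1e-4)
  expect_equal(sqrt(f1$estimates[["sigma1"]]), f3$estimates[["theta4"]], tolerance = 1e-4)
})

test_that("malformed datasets are rejected with typed conditions", {
  ds <- toy_dataset("additive", n = 3, seed = 2)
  pop <- truth_params(attr(ds, "protocol"), "ADD.1")
  expect_error(
    foce_ofv(ds[, setdiff(names(ds), "DV")], pop, error_coding("ADD.1")),
    class = "ruvdiag_format_error"
  )
  expect_error(
    foce_ofv(ds[ds$EVID == 1, ], pop, error_coding("ADD.1")),
    class = "ruvdiag_format_error"
  )
  expect_error(
    foce_ofv(ds[ds$EVID == 0, ], pop, error_coding("ADD.1")),
    class = "ruvdiag_format_error"
  )
})
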