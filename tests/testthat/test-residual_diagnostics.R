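# Diagnostic residuals: definitions, W-(in)dependence, shrinkage.

test_that("the diagnostics table satisfies its defining identities", {
  ds <- toy_dataset("additive", n = 20, seed = 13)
  pop <- truth_params(attr(ds, "protocol"), "ADD.1")
  d <- nm_diagnostics(ds, pop, error_coding("ADD.1"))
  expect_s3_class(d, "nm_diag")
  expect_equal(nrow(d), 240)
  expect_true(all(c("ID", "TIME", "DV", "IPRED", "IWRES", "WRES", "CWRESI", "PRED", "RES") %in% names(d)))
  # IRES = DV - IPRED and IWRES * W = IRES, row by row
  expect_equal(d$IRES, d$DV - d$IPRED, tolerance = 1e-14)
  expect_equal(d$IWRES * d$W, d$IRES, tolerance = 1e-14)
  # RES = DV - PRED with PRED the typical-subject prediction
  expect_equal(d$PRED, pk_conc(d$TIME, 100, 5, 50, 1), tolerance = 1e-12)
  expect_equal(d$RES, d$DV - d$PRED, tolerance = 1e-14)
  # normalized coding: W is the constant residual SD
  expect_equal(d$W, rep(0.5, 240))
})

test_that("the unit-W coding leaves IRES unscaled", {
  ds <- toy_dataset("additive", n = 10, seed = 14)
  pop <- truth_params(attr(ds, "protocol"), "ADD.2")
  d <- nm_diagnostics(ds, pop, error_coding("ADD.2"))
  expect_identical(d$IWRES, d$IRES)
  iw <- implicit_w(d)
  expect_equal(attr(iw, "mean"), 1, tolerance = 1e-15)
  expect_equal(attr(iw, "sd"), 0, tolerance = 1e-15)
})

test_that("WRES and CWRESI are invariant to the W definition at fixed parameters", {
  # the central claim: W enters IWRES only; the likelihood-based residuals
  # depend on the variance model, which these coding pairs share
  ds <- toy_dataset("additive", n = 20, seed = 15)
  proto <- attr(ds, "protocol")
  a1 <- nm_diagnostics(ds, truth_params(proto, "ADD.1"), error_coding("ADD.1"))
  a2 <- nm_diagnostics(ds, truth_params(proto, "ADD.2"), error_coding("ADD.2"))
  a3 <- nm_diagnostics(ds, truth_params(proto, "ADD.3"), error_coding("ADD.3"))
  expect_identical(a1$WRES, a2$WRES)
  expect_identical(a1$CWRESI, a2$CWRESI)
  expect_equal(a1$WRES, a3$WRES, tolerance = 1e-12)
  expect_equal(a1$CWRESI, a3$CWRESI, tolerance = 1e-12)

  dsp <- toy_dataset("proportional", n = 20, seed = 16)
  protop <- attr(dsp, "protocol")
  p1 <- nm_diagnostics(dsp, truth_params(protop, "PROP.1"), error_coding("PROP.1"))
  p2 <- nm_diagnostics(dsp, truth_params(protop, "PROP.2"), error_coding("PROP.2"))
  expect_identical(p1$WRES, p2$WRES)
  expect_identical(p1$CWRESI, p2$CWRESI)
})

test_that("IWRES of paired codings differ by the omitted scale exactly", {
  ds <- toy_dataset("additive", n = 20, seed = 15)
  proto <- attr(ds, "protocol")
  a1 <- nm_diagnostics(ds, truth_params(proto, "ADD.1"), error_coding("ADD.1"))
  a2 <- nm_diagnostics(ds, truth_params(proto, "ADD.2"), error_coding("ADD.2"))
  # IWRES(unit W) = IWRES(normalized) * sqrt(sigma1): constant ratio, r = 1
  expect_equal(a2$IWRES, a1$IWRES * 0.5, tolerance = 1e-14)
  expect_equal(cor(a1$IWRES, a2$IWRES), 1, tolerance = 1e-12)
  expect_equal(sd(a2$IWRES) / sd(a1$IWRES), 0.5, tolerance = 1e-12)

  dsp <- toy_dataset("proportional", n = 20, seed = 16)
  protop <- attr(dsp, "protocol")
  p1 <- nm_diagnostics(dsp, truth_params(protop, "PROP.1"), error_coding("PROP.1"))
  p2 <- nm_diagnostics(dsp, truth_params(protop, "PROP.2"), error_coding("PROP.2"))
  expect_equal(p2$IWRES, p1$IWRES * 0.2, tolerance = 1e-13)
})

test_that("with Omega = 0 the weighted residuals reduce to scaled RES", {
  ds <- toy_dataset("additive", n = 10, seed = 18)
  pop <- pop_params(5, 50,
    ka = 1, omega2_cl = 0, omega2_v = 0,
    err = err_params(sigma1 = 0.25)
  )
  d <- nm_diagnostics(ds, pop, error_coding("ADD.1"))
  # no random effects: V is diagonal, WRES = RES / sqrt(sigma1), CWRESI = WRES,
  # and the conditional prediction equals the typical prediction
  expect_equal(d$IPRED, d$PRED, tolerance = 1e-14)
  expect_equal(d$WRES, d$RES / 0.5, tolerance = 1e-12)
  expect_equal(d$CWRESI, d$WRES, tolerance = 1e-12)
})

test_that("correctly specified weighted residuals have unit spread", {
  # Omega = 0 makes the whitening exact, so SD(WRES) estimates 1 with
  # Monte-Carlo error ~ 1/sqrt(2 * n_obs)
  ds <- toy_dataset("additive",
    n = 500, seed = 27,
    omega2_cl = 0, omega2_v = 0, sigma_add = 0.1
  )
  pop <- pop_params(5, 50,
    ka = 1, omega2_cl = 0, omega2_v = 0,
    err = err_params(sigma1 = 0.01)
  )
  d <- nm_diagnostics(ds, pop, error_coding("ADD.1"))
  expect_equal(sd(d$WRES), 1, tolerance = 0.05)
  expect_lt(abs(mean(d$WRES)), 0.05)
})

test_that("epsilon-shrinkage is one minus the IWRES standard deviation", {
  x <- c(-0.947, 0.947) / sqrt(2)
  expect_equal(sd(x), 0.947, tolerance = 1e-15)
  expect_equal(epsilon_shrinkage(x), 0.053, tolerance = 1e-12)
  expect_equal(epsilon_shrinkage(c(-0.933, 0.933) / sqrt(2)), 0.067, tolerance = 1e-12)
  expect_error(epsilon_shrinkage(1), class = "ruvdiag_configuration_error")
  # accepts a diagnostics table directly
  ds <- toy_dataset("additive", n = 10, seed = 18)
  d <- nm_diagnostics(ds, truth_params(attr(ds, "protocol"), "ADD.1"), error_coding("ADD.1"))
  expect_equal(epsilon_shrinkage(d), 1 - sd(d$IWRES), tolerance = 1e-14)
})

test_that("component wrappers and CSV export expose the canonical columns", {
  ds <- toy_dataset("combined", n = 6, seed = 9)
  pop <- truth_params(attr(ds, "protocol"), "COMB_VAR1")
  coding <- error_coding("COMB_VAR1")
  expect_identical(
    names(individual_residuals(ds, pop, coding)),
    c("ID", "TIME", "IPRED", "IRES", "IWRES")
  )
  expect_identical(
    names(population_residuals(ds, pop, coding)),
    c("ID", "TIME", "PRED", "RES", "WRES")
  )
  expect_identical(names(conditional_residuals(ds, pop, coding)), c("ID", "TIME", "CWRESI"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagnostics(nm_diagnostics(ds, pop, coding), path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(
    names(out),
    c("ID", "TIME", "DV", "IPRED", "IWRES", "WRES", "CWRESI", "PRED", "RES")
  )
})
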