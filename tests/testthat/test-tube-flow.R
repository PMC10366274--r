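test_that("Newtonian limit recovers Hagen-Poiseuille to 1e-10 relative", {
  for (case in list(c(R = 2e-3, L = 0.1, mu = 1, dP = 1e5),
                    c(R = 4.85e-3, L = 0.06, mu = 100, dP = 3e6),
                    c(R = 1.6e-3, L = 0.1, mu = 0.01, dP = 50))) {
    seg <- tube_segment(case[["R"]], case[["L"]])
    p <- newtonian_params(case[["mu"]])
    Q_hp <- pi * case[["R"]]^4 * case[["dP"]] / (8 * case[["mu"]] * case[["L"]])
    expect_equal(tube_flowrate(p, seg, case[["dP"]]), Q_hp,
                 tolerance = 1e-10)
    expect_equal(tube_pressure(p, seg, Q_hp), case[["dP"]],
                 tolerance = 1e-10)
  }
  expect_identical(tube_flowrate(cement_fix(), tube_segment(1e-3, 0.1), 0), 0)
  expect_identical(tube_pressure(cement_fix(), tube_segment(1e-3, 0.1), 0), 0)
})

test_that("power-law regime matches the closed-form pipe solution within 1%", {
  # deep in the shear-thinning branch the Carreau fluid behaves as a power
  # law with consistency k = mu0 * lambda_rh^(n-1)
  n <- 0.5
  p <- carreau_params(100, 1e-8, 1, n)
  seg <- tube_segment(2e-3, 0.1)
  dP <- 5e6   # wall shear rates ~1e4-1e5 >> 1/lambda
  k <- p$mu0 * p$lambda_rh^(n - 1)
  Q_pl <- (pi * seg$radius^3 * n / (3 * n + 1)) *
    (seg$radius * dP / (2 * seg$length * k))^(1 / n)
  expect_equal(tube_flowrate(p, seg, dP), Q_pl, tolerance = 0.01)
})

test_that("flow rate is strictly increasing in pressure and inverts cleanly", {
  cem <- cement_fix()
  seg <- tube_segment(1.6e-3, 0.1)
  dP <- 10^seq(3, 7, length.out = 25)
  Q <- vapply(dP, function(d) tube_flowrate(cem, seg, d), numeric(1))
  expect_true(all(diff(Q) > 0))
  # roundtrip dP -> Q -> dP
  for (d in c(1e4, 1e5, 3e6)) {
    Qd <- tube_flowrate(cem, seg, d)
    expect_equal(tube_pressure(cem, seg, Qd), d, tolerance = 1e-6)
  }
})

test_that("series assembly pressure is additive", {
  cem <- cement_fix()
  s1 <- tube_segment(2e-3, 0.05)
  s2 <- tube_segment(1.5e-3, 0.02)
  s3 <- tube_segment(4e-3, 0.08)
  Q <- 0.3e-6
  expect_equal(assembly_pressure(cem, list(s1), Q),
               tube_pressure(cem, s1, Q))
  expect_equal(assembly_pressure(cem, list(s1, s1), Q),
               2 * tube_pressure(cem, s1, Q), tolerance = 1e-12)
  expect_equal(assembly_pressure(cem, list(s1, s2, s3), Q),
               tube_pressure(cem, s1, Q) + tube_pressure(cem, s2, Q) +
                 tube_pressure(cem, s3, Q), tolerance = 1e-12)
  expect_error(assembly_pressure(cem, list(), Q), "empty")
})

test_that("Carreau exponents are recovered from synthetic injections", {
  segs <- default_assembly_segments()
  truth <- cement_fix()
  obs <- lapply(c(0.1e-6, 0.4e-6), function(Q)
    list(flow_rate = Q, pressure = assembly_pressure(truth, segs, Q)))
  fit <- fit_carreau_exponents(obs[[1]], obs[[2]], truth$mu0, truth$mu_inf,
                               segs)
  expect_equal(fit$lambda_rh, 1.38, tolerance = 1e-4)
  expect_equal(fit$n_rh, 0.30, tolerance = 1e-4)
  expect_false(fit$boundary)
})

test_that("Newtonian data drives the fit to the n_rh -> 1 boundary", {
  segs <- default_assembly_segments()
  mu <- 50
  newt <- newtonian_params(mu)
  obs <- lapply(c(0.1e-6, 0.4e-6), function(Q)
    list(flow_rate = Q, pressure = assembly_pressure(newt, segs, Q)))
  # pressures exactly proportional to Q, consistent with the zero-shear
  # plateau: the only Carreau member fitting both is the Newtonian limit
  fit <- fit_carreau_exponents(obs[[1]], obs[[2]], mu0 = mu, mu_inf = 1,
                               segs)
  expect_true(fit$boundary || fit$n_rh > 0.98)
})

test_that("the fit degrades gracefully under 1% observation noise", {
  segs <- default_assembly_segments()
  truth <- cement_fix()
  set.seed(11)
  obs <- lapply(c(0.1e-6, 0.4e-6), function(Q)
    list(flow_rate = Q,
         pressure = assembly_pressure(truth, segs, Q) * (1 + 0.01 * rnorm(1))))
  fit <- fit_carreau_exponents(obs[[1]], obs[[2]], truth$mu0, truth$mu_inf,
                               segs)
  expect_true(is.finite(fit$lambda_rh) && is.finite(fit$n_rh))
  expect_equal(fit$lambda_rh, 1.38, tolerance = 0.5)
  expect_equal(fit$n_rh, 0.30, tolerance = 0.3)
})
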