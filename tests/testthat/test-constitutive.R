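test_that("Carreau viscosity hits its limits and the transition value", {
  cem <- cement_fix()
  # zero-shear plateau
  expect_identical(carreau_viscosity(cem, 0), 1930)
  # n_rh = 1 collapses to Newtonian regardless of shear rate
  newt <- carreau_params(10, 1, 2, 1)
  expect_equal(carreau_viscosity(newt, c(0, 1, 1e6)), rep(10, 3))
  # value at the transition shear rate 1/lambda_rh, frozen from
  # high-precision evaluation of mu_inf + (mu0-mu_inf) * 2^((n-1)/2)
  expect_equal(carreau_viscosity(cem, 1 / 1.38), 1514.663061631788,
               tolerance = 1e-12)
})

test_that("Carreau viscosity is non-increasing and bounded on a fine grid", {
  cem <- cement_fix()
  g <- 10^seq(-6, 8, length.out = 1000)
  mu <- carreau_viscosity(cem, g)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= cem$mu_inf & mu <= cem$mu0))
})

test_that("carreau_params rejects invalid parameters", {
  expect_error(carreau_params(1, 2), "mu0 >= mu_inf")
  expect_error(carreau_params(1, 0.5, -1), "lambda_rh")
  expect_error(carreau_params(1, 0.5, 1, 0), "n_rh")
  expect_error(carreau_params(1, 0.5, 1, 1.5), "n_rh")
  expect_error(carreau_viscosity(cement_fix(), -1), "gamma_dot")
})

test_that("Brooks-Corey endpoints, hand value, monotonicity and bounds", {
  expect_equal(brooks_corey(3, 0), list(kr_C = 1, kr_M = 0))
  expect_equal(brooks_corey(3, 1), list(kr_C = 0, kr_M = 1))
  # lambda_bc = 2, sM = 0.5: kr_M = 0.5^4, kr_C = 0.25 * (1 - 0.25)
  bc <- brooks_corey(2, 0.5)
  expect_equal(bc$kr_C, 0.1875, tolerance = 1e-14)
  expect_equal(bc$kr_M, 0.0625, tolerance = 1e-14)
  s <- seq(0, 1, length.out = 201)
  for (lam in c(0.1, 1, 3, 10)) {
    kr <- brooks_corey(lam, s)
    expect_true(all(kr$kr_C >= 0 & kr$kr_C <= 1))
    expect_true(all(kr$kr_M >= 0 & kr$kr_M <= 1))
    expect_true(all(diff(kr$kr_C) <= 1e-14))
    expect_true(all(diff(kr$kr_M) >= -1e-14))
  }
  expect_error(brooks_corey(3, 1.2), "sM")
})

test_that("Hooke stress matches a component-wise oracle", {
  expect_equal(hooke_stress(1e9, 2e9, matrix(0, 3, 3)), matrix(0, 3, 3))
  # isotropic strain e*I -> (2 mu + 3 lambda) e I ... trace part
  e <- 1e-4
  sig <- hooke_stress(3e9, 2e9, diag(3) * e)
  expect_equal(sig, (2 * 3e9 + 3 * 2e9) * e * diag(3))
  # pure shear
  eps <- matrix(0, 3, 3); eps[1, 2] <- eps[2, 1] <- 1e-5
  sig <- hooke_stress(5e9, 7e9, eps)
  expect_equal(sig[1, 2], 2 * 5e9 * 1e-5)
  expect_equal(sum(diag(sig)), 0)
  # random symmetric tensors against an explicit loop
  set.seed(42)
  for (k in 1:6) {
    a <- matrix(rnorm(9), 3, 3)
    eps <- (a + t(a)) / 2
    mu <- runif(1, 1e8, 1e11); la <- runif(1, 1e8, 1e11)
    sig <- hooke_stress(mu, la, eps)
    oracle <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      oracle[i, j] <- 2 * mu * eps[i, j] +
        la * (eps[1, 1] + eps[2, 2] + eps[3, 3]) * (i == j)
    expect_equal(sig, oracle, tolerance = 1e-12)
  }
  expect_error(hooke_stress(1, 1, matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("solid volume fraction follows the linearized volume balance", {
  expect_equal(solid_volume_fraction(0.08, 0), 0.08)
  expect_equal(solid_volume_fraction(0.5, 0.25), 0.4)
  # expansion dilutes the solid monotonically
  dv <- seq(0, 0.1, length.out = 50)
  expect_true(all(diff(solid_volume_fraction(0.08, dv)) < 0))
  expect_error(solid_volume_fraction(0.1, -1), "degenerate")
})

test_that("phase fractions satisfy the saturation conditions exactly", {
  pf <- phase_fractions(0.08, 1)
  expect_equal(pf$nM, 0.92)
  expect_equal(pf$nC, 0)
  pf <- phase_fractions(0.08, 0)
  expect_equal(pf$nC, 0.92)
  pf <- phase_fractions(0.2, 0.25)
  expect_equal(pf$nC, 0.6)
  expect_equal(pf$nM, 0.2)
  expect_equal(pf$nS + pf$nC + pf$nM, 1)
  set.seed(7)
  nS <- runif(200, 0.01, 0.99)
  sM <- runif(200)
  pf <- phase_fractions(nS, sM)
  expect_equal(pf$nS + pf$nC + pf$nM, rep(1, 200), tolerance = 1e-15)
  expect_equal(pf$sC + pf$sM, rep(1, 200), tolerance = 1e-15)
  expect_error(phase_fractions(0, 0.5), "nS")
})
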