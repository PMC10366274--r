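test_that("effective shear rate: zero flow, linearity, model-constant ratio", {
  expect_identical(effective_shear_rate(6, 0.3, 0, 0.92, 1, 2.1e-9), 0)
  g1 <- effective_shear_rate(6, 0.3, 1e-3, 0.92, 1, 2.1e-9)
  expect_equal(effective_shear_rate(6, 0.3, 2e-3, 0.92, 1, 2.1e-9), 2 * g1)
  g2 <- effective_shear_rate(0.69, 0.3, 1e-3, 0.92, 1, 2.1e-9)
  expect_equal(g1 / g2, 6 / 0.69, tolerance = 1e-14)
  # frozen from high-precision evaluation at the foam parameters
  expect_equal(g1, 145.8543900015236, tolerance = 1e-12)
})

test_that("semi-empirical viscosity: plateaus, monotonicity, kr*K product", {
  ch <- upscaling_choice("cannella")
  cem <- cement_fix()
  expect_equal(semi_empirical_viscosity(ch, cem, 0, 0.92, 1, 2.1e-9),
               cem$mu0)
  expect_equal(semi_empirical_viscosity(ch, newtonian_params(7), 1, 0.9, 1,
                                        1e-9), 7)
  w <- 10^seq(-8, 1, length.out = 200)
  mu <- semi_empirical_viscosity(ch, cem, w, 0.92, 1, 2.1e-9)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= cem$mu_inf & mu <= cem$mu0))
  # dependence on kr and K_S only through the product kr*K_S
  a <- semi_empirical_viscosity(ch, cem, 1e-3, 0.92, 0.5, 2e-9)
  b <- semi_empirical_viscosity(ch, cem, 1e-3, 0.92, 1.0, 1e-9)
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("average viscosity: Newtonian exact, zero-flow plateau, quadrature oracle", {
  expect_equal(average_viscosity(newtonian_params(3.3), 1e-3, c(0, 0.1, 5)),
               rep(3.3, 3))
  cem <- cement_fix()
  expect_equal(average_viscosity(cem, 0.32e-3, 0), cem$mu0)
  # independent oracle of the same definition with adaptive quadrature and
  # per-point shear-stress inversion
  oracle <- function(params, R, v) {
    Q <- v * pi * R^2
    G <- stats::uniroot(function(g)
      tube_flowrate(params, tube_segment(R, 1), g) - Q,
      c(1e-8, 1e14), tol = 1e-12)$root
    f <- function(r) {
      vapply(r, function(ri) {
        tau <- G * ri / 2
        if (tau == 0) return(params$mu0 * ri)
        gam <- stats::uniroot(function(g)
          carreau_viscosity(params, g) * g - tau,
          c(tau / params$mu0, tau / params$mu_inf), tol = 1e-16)$root
        carreau_viscosity(params, gam) * ri
      }, numeric(1))
    }
    2 / R^2 * stats::integrate(f, 0, R, rel.tol = 1e-12)$value
  }
  v_bench <- 0.4e-6 / (pi * (1.6e-3)^2)   # benchmark inlet velocity scale
  for (v in c(1e-4, v_bench)) {
    expect_equal(average_viscosity(cem, 0.32e-3, v),
                 oracle(cem, 0.32e-3, v), tolerance = 1e-6)
  }
  mu <- average_viscosity(cem, 0.32e-3, 10^seq(-6, 0, length.out = 15))
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= cem$mu_inf & mu <= cem$mu0))
})

test_that("phase dispatcher routes to the correct model", {
  cem <- cement_fix()
  args <- list(w_mag = 2e-3, n_beta = 0.9, kr = 0.7, K_S = 2.1e-9,
               R_char = 0.32e-3)
  can <- do.call(phase_effective_viscosity,
                 c(list(upscaling_choice("cannella"), cem), args))
  expect_equal(can, semi_empirical_viscosity(upscaling_choice("cannella"),
                                             cem, 2e-3, 0.9, 0.7, 2.1e-9))
  hp <- do.call(phase_effective_viscosity,
                c(list(upscaling_choice("hirasaki_pope"), cem), args))
  expect_equal(hp, semi_empirical_viscosity(upscaling_choice("hirasaki_pope"),
                                            cem, 2e-3, 0.9, 0.7, 2.1e-9))
  av <- do.call(phase_effective_viscosity,
                c(list(upscaling_choice("average_viscosity"), cem), args))
  expect_equal(av, average_viscosity(cem, 0.32e-3, 2e-3))
  # identical inputs give identical outputs for the two phases
  expect_equal(can,
               do.call(phase_effective_viscosity,
                       c(list(upscaling_choice("cannella"), cem), args)))
  expect_error(upscaling_choice("something_else"))
})

test_that("tabulated face viscosity solves the local fixed point", {
  # the solver's per-face lookup mu(X) must satisfy mu = carreau(X / mu)
  # (semi-empirical models) across the whole shear-thinning transition
  cem <- cement_fix()
  med <- foam_fix()
  fn <- vertebropm:::.build_face_mu_fn(upscaling_choice("cannella"), cem, med)
  X <- 10^seq(-6, 8, length.out = 60)
  mu <- fn(X)
  resid <- abs(mu - carreau_viscosity(cem, X / mu)) / mu
  expect_lt(max(resid), 1e-5)
})
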