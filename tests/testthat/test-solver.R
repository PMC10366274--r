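test_that("Darcy phase flux follows the mobility-scaled pressure gradient", {
  expect_equal(darcy_phase_flux(c(0, 0, 0), 1, 2.1e-9, 1), c(0, 0, 0))
  f1 <- darcy_phase_flux(c(1e5, 0, 0), 0.5, 2.1e-9, 1)
  f2 <- darcy_phase_flux(c(1e5, 0, 0), 1.0, 2.1e-9, 1)
  expect_equal(f2, 2 * f1)
  # hand value: kr=1, K=2.1e-9, mu=1, |grad p|=1e5 -> 2.1e-4 m/s, against it
  expect_equal(f2[1], -2.1e-4, tolerance = 1e-14)
  expect_error(darcy_phase_flux(c(1, 0, 0), 1, 1e-9, 0))
})

test_that("an undisturbed state is a discrete equilibrium", {
  sys <- column_system(nx = 5)
  st0 <- mixture_state(sys$topo)
  st1 <- st0; st1$t <- 1
  r <- assemble_residual(sys, st1, st0)
  expect_equal(max(abs(r)), 0)
  # uniform nonzero pressure with an arbitrary saturation pattern:
  # no pressure gradient means no flux and no storage change
  set.seed(3)
  st0$p[] <- 740
  st0$sM <- runif(sys$nv)
  st1 <- st0; st1$t <- 1
  sys0 <- column_system(nx = 5)
  # bypass Dirichlet rows by checking only interior residual entries
  r <- assemble_residual(sys0, st1, st0)
  free <- setdiff(seq_len(sys0$ndof), sys0$dir_dofs)
  fluid <- free[(free - 1) %% 5 + 1 >= 4]
  expect_lt(max(abs(r[fluid])), 1e-20)
})

test_that("prescribed inflow enters the cement balance as a boundary source", {
  # single cell, inflow on one face: with state_new = state_old the cement
  # residual at each inlet vertex is minus its sub-area share of Q
  mesh <- generate_box_mesh(1, 1, 1, dims = c(0.01, 0.01, 0.01),
                            tags = c(xmin = "inlet", xmax = "outer_wall"))
  topo <- build_box_topology(mesh)
  Q <- 3e-8
  bcs <- boundary_conditions(dirichlet_p = c(outer_wall = 0),
                             dirichlet_sM = c(outer_wall = 1),
                             dirichlet_u_tags = "all",
                             inflow = c(inlet = Q))
  sys <- build_injection_system(topo, foam_fix(), cement_fix(), air_fix(),
                                upscaling_choice("cannella"), bcs)
  st0 <- mixture_state(topo)
  st1 <- st0; st1$t <- 0.25
  r <- assemble_residual(sys, st1, st0)
  inlet_v <- sys$inflow_vertices
  pd <- (inlet_v - 1) * 5 + 4
  expect_equal(sort(r[pd]), rep(-Q / 4, 4), tolerance = 1e-12)
  # total prescribed inflow equals Q by construction
  expect_equal(sum(-r[pd]), Q, tolerance = 1e-14)
})

test_that("single-phase column reproduces the linear Darcy solution", {
  mu <- 1e-3
  K <- 1e-10
  L <- 0.1
  A <- 0.01^2
  dP <- 1000
  sys <- column_system(nx = 20, L = L, A_side = 0.01, p_in = dP,
                       marrow = newtonian_params(mu))
  st0 <- mixture_state(sys$topo)
  stp <- newton_step(sys, st0, dt = 1)
  expect_true(stp$converged)
  # a linear problem converges essentially in one Newton update
  expect_lte(stp$iterations, 3)
  xs <- sys$mesh$vertices[, 1]
  expect_equal(stp$state$p, dP * (1 - xs / L), tolerance = 1e-8)
  # flux through the mid cross-section against the closed form
  Q_exact <- K / mu * A * dP / L
  st <- stp$state
  P <- matrix(st$p[sys$cells], sys$nc, 8)
  S <- matrix(st$sM[sys$cells], sys$nc, 8)
  loc <- vertebropm:::.fluid_local(sys, P, S, P, S,
                                   numeric(sys$nc), numeric(sys$nc), 1)
  # marrow flux: recompute from the Darcy law at cell centres
  gp <- rowSums(sys$g0[[1]] * P)
  q_cell <- -K / mu * gp * A
  expect_equal(q_cell, rep(Q_exact, sys$nc), tolerance = 1e-8)
  # re-converging a perturbed state returns to the same solution
  st2 <- stp$state
  set.seed(5)
  st2$p <- st2$p + rnorm(sys$nv, sd = 1e-3 * dP)
  stp2 <- newton_step(sys, st0, dt = 1, state0 = st2)
  expect_true(stp2$converged)
  expect_equal(stp2$state$p, stp$state$p, tolerance = 1e-6)
})

test_that("two-phase 1D displacement matches the Buckley-Leverett oracle", {
  # constant viscosities, lambda_bc = 2, inflow-driven 100-cell column;
  # the Welge-tangent fractional-flow construction is the oracle
  fr <- bl_front_positions()
  expect_gt(fr[["exact"]], 0.25 * fr[["L"]])
  expect_lt(fr[["exact"]], 0.9 * fr[["L"]])
  expect_equal(fr[["sim"]], fr[["exact"]], tolerance = 0.05)
})

test_that("injection keeps saturations essentially within physical bounds", {
  run <- clinical_run_lowvisc()
  ts <- run$timeseries
  expect_true(all(run$final$sM >= 0 & run$final$sM <= 1))
  # clamping beyond the 1e-8 guard band is rare across all Newton updates
  expect_lt(sum(ts$clamped), 0.01 * length(run$final$sM) * nrow(ts))
})

test_that("an extremely stiff skeleton leaves the fluid solution unchanged", {
  base <- column_system(nx = 30, inflow = 2e-9,
                        controls = solver_controls(dt = 50),
                        u_tags = "xmin")
  med_stiff <- medium_params(K_S = 1e-10, n_F = 0.5, lambda_bc = 2,
                             R_char = 1e-4, mu_lame = 1e11,
                             lambda_lame = 1e11)
  stiff <- column_system(nx = 30, medium = med_stiff, inflow = 2e-9,
                         controls = solver_controls(dt = 50),
                         u_tags = "xmin")
  r1 <- time_march(base, 500)
  r2 <- time_march(stiff, 500)
  expect_equal(r2$final$p, r1$final$p, tolerance = 1e-3)
  expect_equal(r2$final$sM, r1$final$sM, tolerance = 1e-3)
})

test_that("a zero-inflow scenario stays constant in time", {
  sys <- column_system(nx = 8, controls = solver_controls(dt = 10))
  out <- tempfile("snaps")
  res <- time_march(sys, 30, snapshot_times = c(10, 20, 30), out_dir = out)
  expect_equal(max(abs(res$final$p)), 0)
  expect_equal(res$final$sM, rep(1, sys$nv))
  expect_equal(res$timeseries$cement_volume,
               rep(0, nrow(res$timeseries)), tolerance = 1e-20)
  # snapshots: one file per requested time, zero-padded indices
  expect_equal(basename(res$snapshots),
               sprintf("snapshot_%04d.vtk", 1:3))
  expect_true(all(file.exists(res$snapshots)))
  info <- read_vtk_info(res$snapshots[2])
  expect_equal(info$n_points, sys$nv)
  expect_true(all(c("p", "sM", "sC", "mu_C") %in% info$point_data))
})

test_that("halving the time step barely changes the final inlet pressure", {
  base <- benchmark_scenario(flow_rate = 0.4, resolution = "tiny",
                             injected_volume_ml = 1)
  fine <- base
  fine$controls <- solver_controls(dt = 0.125)
  p_base <- run_scenario(base)$timeseries
  p_fine <- run_scenario(fine)$timeseries
  expect_equal(p_fine$inlet_pressure[nrow(p_fine)],
               p_base$inlet_pressure[nrow(p_base)], tolerance = 0.02)
})
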