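test_that("benchmark scenario carries the experiment's material parameters", {
  cfg <- benchmark_scenario(flow_rate = 0.4)
  expect_equal(cfg$medium$K_S, 2.1e-9)
  expect_equal(cfg$medium$n_F, 0.92)
  expect_equal(cfg$medium$lambda_bc, 3)
  expect_equal(cfg$medium$R_char, 0.32e-3)
  expect_equal(cfg$medium$mu_lame, 28.2e9)
  expect_equal(cfg$medium$lambda_lame, 54.7e9)
  expect_equal(cfg$cement$mu0, 1930)
  expect_equal(cfg$cement$mu_inf, 1.93)
  expect_equal(cfg$cement$lambda_rh, 1.38)
  expect_equal(cfg$cement$n_rh, 0.30)
  expect_equal(cfg$marrow$mu0, 1.8e-5)
  # end time = injected volume / flow rate
  expect_equal(cfg$injected_volume / cfg$flow_rate, 5)
  expect_equal(benchmark_scenario(0.1)$injected_volume /
                 benchmark_scenario(0.1)$flow_rate, 20)
  expect_error(benchmark_scenario(0.2), "flow rates")
  expect_s3_class(benchmark_scenario(0.2, allow_custom = TRUE),
                  "scenario_config")
})

test_that("clinical scenario swaps in bone elasticity and marrow rheology", {
  cfg <- clinical_scenario()
  expect_equal(cfg$medium$mu_lame, 3.85e9)
  expect_equal(cfg$medium$lambda_lame, 5.77e9)
  expect_equal(cfg$marrow$mu0, 1000)
  expect_equal(cfg$marrow$mu_inf, 100)   # mu0/mu_inf = 10
  expect_equal(cfg$marrow$lambda_rh, 1)
  expect_equal(cfg$marrow$n_rh, 0.5)
  expect_equal(cfg$initial_sM, 1)
  newt <- clinical_scenario(marrow_mu0 = 0.01, marrow_newtonian = TRUE)
  expect_equal(newt$marrow$mu0, 0.01)
  expect_equal(newt$marrow$mu_inf, 0.01)
})

test_that("injection force combines pressures over the plunger area", {
  expect_equal(injection_force(0, 0), 0)
  f1 <- injection_force(2e5, 1e5, 9.7e-3)
  f2 <- injection_force(2e5, 1e5, 9.7e-3 * sqrt(2))
  expect_equal(f2, 2 * f1)
  # frozen arithmetic oracle: 1e5 Pa on a 9.7 mm plunger
  expect_equal(injection_force(1e5, 0, 9.7e-3), 7.389811319406591,
               tolerance = 1e-12)
})

test_that("scenario configs round-trip through the YAML format", {
  cfg <- clinical_scenario(marrow = carreau_params(120, 12, 1, 0.5),
                           resolution = "tiny",
                           controls = solver_controls(dt = 0.1,
                                                      newton_tol = 1e-7))
  path <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$medium, cfg$medium, tolerance = 1e-12)
  expect_equal(back$cement, cfg$cement, tolerance = 1e-12)
  expect_equal(back$marrow, cfg$marrow, tolerance = 1e-12)
  expect_equal(back$flow_rate, cfg$flow_rate, tolerance = 1e-12)
  expect_equal(back$injected_volume, cfg$injected_volume, tolerance = 1e-12)
  expect_equal(back$upscaling$model, cfg$upscaling$model)
  expect_equal(back$controls$dt, 0.1)
  expect_equal(back$controls$newton_tol, 1e-7)
  expect_equal(back$geometry, cfg$geometry, tolerance = 1e-12)
  expect_equal(length(back$assembly), length(cfg$assembly))
  expect_equal(back$assembly[[3]]$radius, cfg$assembly[[3]]$radius,
               tolerance = 1e-12)
})

test_that("the front profile of an uninjected state is identically zero", {
  cfg <- benchmark_scenario(resolution = "tiny")
  sys <- vertebropm:::.build_scenario_system(cfg)
  st0 <- mixture_state(sys$topo)
  fp <- front_profile(st0, sys = sys)
  expect_true(all(fp$sC == 0))
  expect_true(is.na(attr(fp, "sharpness")))
})

test_that("tidy/glance/autoplot expose the run results", {
  run <- clinical_run_lowvisc()
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "inlet_pressure", "injection_force",
                    "cement_volume") %in% names(td)))
  expect_true(all(diff(td$time) > 0))
  expect_true(all(diff(td$injected_volume) > 0))
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_equal(g$injected_volume_ml, 2, tolerance = 1e-9)
  p <- ggplot2::autoplot(run)
  expect_s3_class(p, "ggplot")
  fp <- front_profile(run)
  expect_s3_class(ggplot2::autoplot(fp), "ggplot")
})

test_that("the CLI writes meshes and fits rheology", {
  out <- tempfile(fileext = ".vtk")
  mesh <- vpm_cli(c("mesh", "benchmark", "--out", out,
                    "--resolution", "tiny"))
  expect_true(file.exists(out))
  expect_equal(read_vtk_info(out)$n_cells, nrow(mesh$cells))
  # fit-rheology round trip on synthetic observations
  segs <- default_assembly_segments()
  truth <- cement_fix()
  p1 <- assembly_pressure(truth, segs, 0.1e-6)
  p2 <- assembly_pressure(truth, segs, 0.4e-6)
  fit <- vpm_cli(c("fit-rheology",
                   "--pair", sprintf("0.1:%.6g", p1),
                   "--pair", sprintf("0.4:%.6g", p2),
                   "--mu0", "1930", "--muinf", "1.93"))
  expect_equal(fit$lambda_rh, 1.38, tolerance = 1e-3)
  expect_equal(fit$n_rh, 0.30, tolerance = 1e-3)
})
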