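# Shared fixtures: the material parameters of the benchmark experiment
# (aluminium foam + PMMA bone cement + air) and small meshes/systems.

cement_fix <- function() carreau_params(1930, 1.93, 1.38, 0.30)
air_fix <- function() newtonian_params(1.8e-5)
foam_fix <- function() medium_params(K_S = 2.1e-9, n_F = 0.92, lambda_bc = 3,
                                     R_char = 0.32e-3, mu_lame = 28.2e9,
                                     lambda_lame = 54.7e9)

# 1D column system: nx cells along x, two Newtonian fluids, all vertices
# clamped. Either pressure-driven (dirichlet p both ends) or inflow-driven.
column_system <- function(nx = 20, L = 0.1, A_side = 0.01,
                          medium = NULL, cement = NULL, marrow = NULL,
                          p_in = NULL, inflow = NULL,
                          controls = solver_controls(dt = 1),
                          u_tags = "all") {
  if (is.null(medium))
    medium <- medium_params(K_S = 1e-10, n_F = 0.5, lambda_bc = 2,
                            R_char = 1e-4, mu_lame = 1e9, lambda_lame = 1e9)
  if (is.null(cement)) cement <- newtonian_params(5e-3)
  if (is.null(marrow)) marrow <- newtonian_params(1e-3)
  mesh <- generate_box_mesh(nx, 1, 1, dims = c(L, A_side, A_side))
  topo <- build_box_topology(mesh)
  dir_p <- c(xmax = 0)
  dir_s <- c(xmax = 1)
  if (!is.null(p_in)) {
    # pressure-driven column: the upstream face is an inflow boundary, so
    # the composition of the entering fluid must be prescribed there
    dir_p <- c(xmin = p_in, xmax = 0)
    dir_s <- c(xmin = 1, xmax = 1)
  }
  bcs <- boundary_conditions(
    dirichlet_p = dir_p,
    dirichlet_sM = dir_s,
    dirichlet_u_tags = u_tags,
    inflow = if (is.null(inflow)) numeric() else c(xmin = inflow))
  sys <- build_injection_system(topo, medium, cement, marrow,
                                upscaling_choice("cannella"), bcs, controls)
  sys
}

# memoized expensive runs shared between test files (test_dir runs all test
# files in one session, so the cache persists across files)
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, build) {
  if (!exists(key, envir = .run_cache))
    assign(key, build(), envir = .run_cache)
  get(key, envir = .run_cache)
}

benchmark_run_coarse <- function()
  cached_run("benchmark_coarse", function()
    run_scenario(benchmark_scenario(flow_rate = 0.4, resolution = "coarse")))

clinical_run_coarse <- function()
  cached_run("clinical_coarse", function()
    run_scenario(clinical_scenario(marrow = carreau_params(1000, 100, 1, 0.5),
                                   resolution = "coarse")))

clinical_run_lowvisc <- function()
  cached_run("clinical_lowvisc", function()
    run_scenario(clinical_scenario(marrow = newtonian_params(0.01),
                                   resolution = "tiny")))

clinical_run_highvisc <- function()
  cached_run("clinical_highvisc", function()
    run_scenario(clinical_scenario(marrow = newtonian_params(1000),
                                   resolution = "tiny")))

# 1D two-phase displacement vs the Buckley-Leverett fractional-flow oracle:
# returns the simulated and exact front positions [m]
bl_front_positions <- function()
  cached_run("bl_front", function() {
    nx <- 100; L <- 0.1; side <- 0.01; A <- side^2
    nF <- 0.5; muC <- 5e-3; muM <- 1e-3
    q <- 2e-9 / A
    med <- medium_params(K_S = 1e-10, n_F = nF, lambda_bc = 2,
                         R_char = 1e-4, mu_lame = 1e9, lambda_lame = 1e9)
    sys <- column_system(nx = nx, L = L, A_side = side, medium = med,
                         cement = newtonian_params(muC),
                         marrow = newtonian_params(muM),
                         inflow = q * A,
                         controls = solver_controls(dt = 20))
    t_end <- 1200
    res <- time_march(sys, t_end)
    fC <- function(sC) {
      krC <- sC^2 * (1 - (1 - sC)^2)
      krM <- (1 - sC)^4
      (krC / muC) / (krC / muC + krM / muM)
    }
    s_grid <- seq(1e-6, 1, length.out = 20001)
    s_star <- s_grid[which.max(fC(s_grid) / s_grid)]
    x_exact <- q / nF * fC(s_star) / s_star * t_end
    xs <- sys$mesh$vertices[, 1]
    on_line <- which(abs(sys$mesh$vertices[, 2]) < 1e-12 &
                     abs(sys$mesh$vertices[, 3]) < 1e-12)
    o <- order(xs[on_line])
    x <- xs[on_line][o]
    sC <- (1 - res$final$sM)[on_line][o]
    th <- s_star / 2
    i <- which(sC[-length(sC)] >= th & sC[-1] < th)[1]
    x_sim <- x[i] + (x[i + 1] - x[i]) * (sC[i] - th) / (sC[i] - sC[i + 1])
    c(sim = x_sim, exact = x_exact, L = L)
  })
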