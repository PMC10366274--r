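# Ready-made injection scenarios: the aluminium-foam benchmark (displaced
# fluid: air) and the marrow-filled clinical configuration, plus run
# orchestration, injection-force postprocessing, parameter sweeps and
# saturation front profiles.

.mesh_presets <- list(full = c(8L, 5L), coarse = c(4L, 4L), tiny = c(3L, 2L))

.resolve_resolution <- function(resolution) {
  if (is.character(resolution)) {
    if (!resolution %in% names(.mesh_presets))
      stop(sprintf("unknown resolution preset '%s'", resolution),
           call. = FALSE)
    r <- .mesh_presets[[resolution]]
    list(n_radial = r[1], n_layers_half = r[2])
  } else {
    stopifnot(is.list(resolution),
              all(c("n_radial", "n_layers_half") %in% names(resolution)))
    resolution
  }
}

#' Benchmark injection scenario (cement into air-filled aluminium foam)
#'
#' Scenario of 2 ml of shear-thinning bone cement injected into a cylindrical
#' aluminium-foam specimen (40 mm diameter x 30 mm height) through a cannula,
#' at 0.1 or 0.4 ml/s. Material parameters: aluminium skeleton (Lame 28.2 and
#' 54.7 GPa), cement Carreau (mu0 = 1930 Pa s, mu_inf = 1.93 Pa s,
#' lambda_rh = 1.38 s, n_rh = 0.30), displaced fluid air
#' (1.8e-5 Pa s, Newtonian), porosity 0.92, permeability 2.1e-9 m^2,
#' Brooks-Corey lambda_bc = 3, characteristic pore radius 0.32 mm.
#'
#' @param flow_rate Injection rate in ml/s; 0.1 or 0.4 (other values require
#'   `allow_custom = TRUE`).
#' @param upscaling Upscaling model name or an [upscaling_choice()].
#' @param resolution Mesh preset (`"full"` = 2540 cells, `"coarse"` = 688,
#'   `"tiny"` = 200) or a list with `n_radial`, `n_layers_half`.
#' @param controls A [solver_controls()].
#' @param injected_volume_ml Total injected volume \[ml\].
#' @param allow_custom Allow non-standard flow rates.
#' @return An object of class `scenario_config`.
#' @export
benchmark_scenario <- function(flow_rate = 0.4, upscaling = "cannella",
                               resolution = "coarse",
                               controls = solver_controls(),
                               injected_volume_ml = 2,
                               allow_custom = FALSE) {
  if (!allow_custom && !flow_rate %in% c(0.1, 0.4))
    stop("benchmark flow rates are 0.1 or 0.4 ml/s (allow_custom = TRUE to override)",
         call. = FALSE)
  if (is.character(upscaling)) upscaling <- upscaling_choice(upscaling)
  structure(list(
    name = "benchmark",
    geometry = c(list(type = "benchmark", cyl_diameter = 0.040,
                      cyl_height = 0.030, bore_radius = 1.6e-3),
                 .resolve_resolution(resolution)),
    medium = medium_params(K_S = 2.1e-9, n_F = 0.92, lambda_bc = 3,
                           R_char = 0.32e-3, mu_lame = 28.2e9,
                           lambda_lame = 54.7e9),
    cement = carreau_params(1930, 1.93, 1.38, 0.30),
    marrow = newtonian_params(1.8e-5),
    upscaling = upscaling,
    flow_rate = flow_rate * 1e-6,
    injected_volume = injected_volume_ml * 1e-6,
    controls = controls,
    plunger_diameter = 9.7e-3,
    assembly = default_assembly_segments(),
    include_assembly = TRUE,
    initial_sM = 1), class = "scenario_config")
}

#' Clinically oriented scenario (cement into marrow-filled trabecular bone)
#'
#' Same geometry, boundary conditions and cement as the benchmark, with the
#' skeleton elasticity replaced by trabecular-bone values (Lame 3.85 and
#' 5.77 GPa) and the pore space initially saturated with bone marrow. Marrow
#' rheology is either Newtonian (pass a single viscosity) or Carreau with a
#' fixed plateau ratio mu0/mu_inf = 10, lambda_rh = 1 s, n_rh = 0.5 (pass
#' `marrow_mu0`).
#'
#' @param marrow A [carreau_params()]/[newtonian_params()] object, or `NULL`
#'   to build one from `marrow_mu0`/`marrow_newtonian`.
#' @param marrow_mu0 Zero-shear marrow viscosity \[Pa s\] used when `marrow`
#'   is `NULL`.
#' @param marrow_newtonian If `TRUE`, build a Newtonian marrow at
#'   `marrow_mu0`; otherwise Carreau with `mu_inf = mu0/10`.
#' @inheritParams benchmark_scenario
#' @return An object of class `scenario_config`.
#' @export
clinical_scenario <- function(marrow = NULL, marrow_mu0 = 1000,
                              marrow_newtonian = FALSE,
                              flow_rate = 0.4, upscaling = "cannella",
                              resolution = "coarse",
                              controls = solver_controls(),
                              injected_volume_ml = 2) {
  cfg <- benchmark_scenario(flow_rate, upscaling, resolution, controls,
                            injected_volume_ml, allow_custom = TRUE)
  cfg$name <- "clinical"
  cfg$medium <- medium_params(K_S = 2.1e-9, n_F = 0.92, lambda_bc = 3,
                              R_char = 0.32e-3, mu_lame = 3.85e9,
                              lambda_lame = 5.77e9)
  cfg$marrow <- if (!is.null(marrow)) {
    stopifnot(inherits(marrow, "carreau_params"))
    marrow
  } else if (marrow_newtonian) {
    newtonian_params(marrow_mu0)
  } else {
    carreau_params(marrow_mu0, marrow_mu0 / 10, 1, 0.5)
  }
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: Q = %g ml/s, V = %g ml, upscaling = %s\n",
              x$name, x$flow_rate * 1e6, x$injected_volume * 1e6,
              x$upscaling$model))
  invisible(x)
}

#' Plunger force from inlet pressure and assembly pressure drop
#'
#' `F = (p_inlet + dP_assembly) * pi * (d/2)^2`: the force on the syringe
#' plunger that balances the porous-medium inlet pressure plus (optionally)
#' the drop across the syringe-nozzle-cannula assembly.
#'
#' @param inlet_pressure Pore pressure at the injection opening \[Pa\].
#' @param assembly_dP Series pressure drop of the assembly \[Pa\]
#'   (0 for the foam-only force).
#' @param plunger_diameter Syringe plunger diameter \[m\].
#' @return Force \[N\].
#' @export
injection_force <- function(inlet_pressure, assembly_dP = 0,
                            plunger_diameter = 9.7e-3) {
  stopifnot(plunger_diameter > 0)
  (inlet_pressure + assembly_dP) * pi * (plunger_diameter / 2)^2
}

.build_scenario_mesh <- function(cfg) {
  g <- cfg$geometry
  if (g$type == "benchmark") {
    generate_benchmark_mesh(g$cyl_diameter, g$cyl_height, g$bore_radius,
                            g$n_radial, g$n_layers_half)
  } else if (g$type == "box") {
    generate_box_mesh(g$nx, g$ny, g$nz, dims = g$dims,
                      tags = c(xmin = "inlet", xmax = "outer_wall"))
  } else stop("unknown geometry type", call. = FALSE)
}

.build_scenario_system <- function(cfg, topo = NULL) {
  mesh <- if (is.null(topo)) .build_scenario_mesh(cfg) else topo$mesh
  if (is.null(topo)) topo <- build_box_topology(mesh)
  if (cfg$geometry$type == "benchmark") {
    bottom <- which(abs(mesh$vertices[, 3]) < 1e-12)
    bcs <- boundary_conditions(
      dirichlet_p = c(outer_wall = 0),
      dirichlet_sM = c(outer_wall = cfg$initial_sM),
      dirichlet_u_tags = "cannula_wall",
      extra_u_fixed = bottom,
      inflow = c(inlet = cfg$flow_rate))
  } else {
    bcs <- boundary_conditions(
      dirichlet_p = c(outer_wall = 0),
      dirichlet_sM = c(outer_wall = cfg$initial_sM),
      dirichlet_u_tags = "all",
      inflow = c(inlet = cfg$flow_rate))
  }
  build_injection_system(topo, cfg$medium, cfg$cement, cfg$marrow,
                         cfg$upscaling, bcs, cfg$controls)
}

#' Run an injection scenario
#'
#' Builds the mesh, Box topology and monolithic system for a
#' [benchmark_scenario()]/[clinical_scenario()] (or a config read from file),
#' marches to `t_end = injected_volume / flow_rate`, and post-processes the
#' injection force. Optionally writes a CSV time series, VTK snapshots and a
#' JSON run summary.
#'
#' @param cfg A `scenario_config`.
#' @param out_dir Optional output directory.
#' @param n_snapshots Number of evenly spaced VTK snapshots (0 = none;
#'   requires `out_dir`).
#' @param verbose Print per-step progress.
#' @param topo Optional pre-built `box_topology` (reused across sweep runs).
#' @return An object of class `injection_run`: the config, the time-series
#'   tibble (now including `injection_force` \[N\]), the final state, the
#'   assembly pressure drop, and the built system (for post-processing).
#' @export
run_scenario <- function(cfg, out_dir = NULL, n_snapshots = 0,
                         verbose = FALSE, topo = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  sys <- .build_scenario_system(cfg, topo)
  t_end <- cfg$injected_volume / cfg$flow_rate
  snap_times <- if (n_snapshots > 0)
    seq(t_end / n_snapshots, t_end, length.out = n_snapshots) else numeric()
  state0 <- mixture_state(sys$topo, sM = cfg$initial_sM)
  res <- time_march(sys, t_end, state0 = state0, snapshot_times = snap_times,
                    out_dir = out_dir, verbose = verbose)
  assembly_dP <- assembly_pressure(cfg$cement, cfg$assembly, cfg$flow_rate)
  ts <- res$timeseries
  ts$injection_force <- injection_force(
    ts$inlet_pressure,
    if (cfg$include_assembly) assembly_dP else 0,
    cfg$plunger_diameter)
  ts$injection_force_foam <- injection_force(ts$inlet_pressure, 0,
                                             cfg$plunger_diameter)
  run <- structure(list(config = cfg, timeseries = ts, final = res$final,
                        assembly_dP = assembly_dP, system = sys,
                        snapshots = res$snapshots,
                        newton_failures = res$newton_failures),
                   class = "injection_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(ts, file.path(out_dir, "timeseries.csv"),
                     row.names = FALSE)
    s <- glance(run)
    jsonlite::write_json(as.list(s), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.injection_run <- function(x, ...) {
  ts <- x$timeseries
  n <- nrow(ts)
  cat(sprintf("<injection_run> %s, %d steps to t = %g s\n",
              x$config$name, n, ts$time[n]))
  cat(sprintf("  final force %.3g N (foam only %.3g N), injected %.4g ml\n",
              ts$injection_force[n], ts$injection_force_foam[n],
              ts$injected_volume[n] * 1e6))
  invisible(x)
}

#' Sweep one medium parameter in isolation
#'
#' Re-runs a scenario varying exactly one of the intrinsic permeability,
#' porosity or Brooks-Corey uniformity parameter while all other parameters
#' are held fixed. Individual run failures are recorded and the sweep
#' continues.
#'
#' @param base A `scenario_config`.
#' @param parameter One of `"K_S"`, `"n_F"`, `"lambda_bc"`.
#' @param values Parameter values to run.
#' @param verbose Print progress.
#' @return A list of class `parameter_sweep`: `runs` (list of
#'   `injection_run` or `NULL` for failures), `summary` tibble with the
#'   end-time injection force and front sharpness per value.
#' @export
parameter_sweep <- function(base, parameter = c("K_S", "n_F", "lambda_bc"),
                            values, verbose = FALSE) {
  parameter <- match.arg(parameter)
  runs <- vector("list", length(values))
  rows <- list()
  for (i in seq_along(values)) {
    cfg <- base
    m <- cfg$medium
    args <- list(K_S = m$K_S, n_F = m$n_F, lambda_bc = m$lambda_bc,
                 R_char = m$R_char, mu_lame = m$mu_lame,
                 lambda_lame = m$lambda_lame)
    args[[parameter]] <- values[i]
    cfg$medium <- do.call(medium_params, args)
    run <- tryCatch(run_scenario(cfg, verbose = verbose),
                    error = function(e) {
                      warning(sprintf("sweep value %g failed: %s", values[i],
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    runs[[i]] <- run
    ts <- if (is.null(run)) NULL else run$timeseries
    fp <- if (is.null(run)) NULL else front_profile(run)
    rows[[i]] <- tibble::tibble(
      value = values[i],
      force_end = if (is.null(ts)) NA_real_ else
        ts$injection_force[nrow(ts)],
      force_foam_end = if (is.null(ts)) NA_real_ else
        ts$injection_force_foam[nrow(ts)],
      front_sharpness = if (is.null(fp)) NA_real_ else
        attr(fp, "sharpness"),
      failed = is.null(run))
  }
  structure(list(parameter = parameter, runs = runs,
                 summary = do.call(rbind, rows)),
            class = "parameter_sweep")
}

#' @export
print.parameter_sweep <- function(x, ...) {
  cat(sprintf("<parameter_sweep> over %s\n", x$parameter))
  print(x$summary)
  invisible(x)
}

#' Cement-saturation profile along the injection axis
#'
#' Samples the cement saturation at mesh vertices along the horizontal line
#' through the injection point (the bore tip at mid-height), and computes a
#' front-sharpness scalar: the distance between the `s^C = 0.9` and
#' `s^C = 0.1` crossings of the profile (when the profile never reaches 0.9,
#' the thresholds fall back to 0.9 and 0.1 of the profile maximum, so a
#' diffuse front still yields a finite width).
#'
#' @param run An `injection_run` (or a `mixture_state` plus `sys`).
#' @param state Optional state to profile (default: final state of the run).
#' @param sys Optional `injection_system` when `run` is a state.
#' @return A tibble of class `front_profile` with columns `distance` \[m\]
#'   and `sC`, and attribute `sharpness` \[m\].
#' @export
front_profile <- function(run, state = NULL, sys = NULL) {
  if (inherits(run, "injection_run")) {
    sys <- run$system
    if (is.null(state)) state <- run$final
  } else if (inherits(run, "mixture_state")) {
    state <- run
    if (is.null(sys)) stop("front_profile: sys required for a bare state",
                           call. = FALSE)
  }
  V <- sys$mesh$vertices
  g <- attr(sys$mesh, "geometry")
  z0 <- if (!is.null(g)) g$H / 2 else stats::median(V[, 3])
  tol <- 1e-9
  sel <- which(abs(V[, 2]) < tol & abs(V[, 3] - z0) < tol & V[, 1] >= -tol)
  if (length(sel) < 2)
    stop("front_profile: no vertices on the sampling line", call. = FALSE)
  o <- order(V[sel, 1])
  x <- V[sel, 1][o]
  sC <- (1 - pmin(pmax(state$sM, 0), 1))[sel][o]
  prof <- tibble::tibble(distance = x, sC = sC)
  hi <- 0.9; lo <- 0.1
  mx <- max(sC)
  if (mx < hi && mx > 0) { hi <- 0.9 * mx; lo <- 0.1 * mx }
  cross <- function(th) {
    below <- which(sC <= th)
    above <- which(sC >= th)
    if (length(below) == 0 || length(above) == 0) return(NA_real_)
    i <- which(sC[-length(sC)] >= th & sC[-1] < th)
    if (length(i) == 0) return(NA_real_)
    i <- i[1]
    x[i] + (x[i + 1] - x[i]) * (sC[i] - th) / (sC[i] - sC[i + 1])
  }
  sharp <- cross(lo) - cross(hi)
  structure(prof, class = c("front_profile", class(prof)),
            sharpness = as.numeric(sharp), thresholds = c(hi = hi, lo = lo))
}

#' Post-thinning bulk viscosity at the onset of steady injection
#'
#' The bulk-viscosity diagnostic (volume-weighted median of the nodal
#' effective viscosity over the interior region where the phase is the
#' majority pore occupant) is recorded at every time step. For the cement it
#' grows over the course of an injection because the expanding sampling
#' region increasingly contains previously injected, now quasi-stagnant
#' cement relaxing back towards its zero-shear plateau. The post-thinning
#' viscosity of the cement actually being driven through the pore space is
#' therefore read at the onset of steady injection: the earliest recorded
#' step at which the diagnostic region exists.
#'
#' @param run An `injection_run`.
#' @param phase `"cement"` or `"marrow"`.
#' @return Effective viscosity \[Pa s\].
#' @export
steady_bulk_viscosity <- function(run, phase = c("cement", "marrow")) {
  phase <- match.arg(phase)
  col <- if (phase == "cement") "bulk_visc_cement" else "bulk_visc_marrow"
  v <- run$timeseries[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  v[1]
}
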