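# Scenario configuration files: YAML with explicit unit-suffixed keys.
# Internally everything is strict SI; the file format uses mm, ml/s and GPa
# where practitioners would, converted on load.

.carreau_to_list <- function(p)
  list(mu0_Pa_s = p$mu0, mu_inf_Pa_s = p$mu_inf, lambda_rh_s = p$lambda_rh,
       n_rh = p$n_rh)

.carreau_from_list <- function(l)
  carreau_params(l$mu0_Pa_s, l$mu_inf_Pa_s, l$lambda_rh_s, l$n_rh)

#' Write a scenario configuration to a YAML file
#'
#' @param cfg A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_scenario_config()]
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  g <- cfg$geometry
  m <- cfg$medium
  ctl <- cfg$controls
  out <- list(
    name = cfg$name,
    geometry = list(type = g$type,
                    cyl_diameter_mm = g$cyl_diameter * 1e3,
                    cyl_height_mm = g$cyl_height * 1e3,
                    bore_radius_mm = g$bore_radius * 1e3,
                    n_radial = g$n_radial,
                    n_layers_half = g$n_layers_half),
    medium = list(K_S_m2 = m$K_S, porosity = m$n_F, lambda_bc = m$lambda_bc,
                  R_char_mm = m$R_char * 1e3, mu_lame_GPa = m$mu_lame / 1e9,
                  lambda_lame_GPa = m$lambda_lame / 1e9),
    cement = .carreau_to_list(cfg$cement),
    marrow = .carreau_to_list(cfg$marrow),
    upscaling = cfg$upscaling$model,
    flow_rate_ml_per_s = cfg$flow_rate * 1e6,
    injected_volume_ml = cfg$injected_volume * 1e6,
    plunger_diameter_mm = cfg$plunger_diameter * 1e3,
    include_assembly = cfg$include_assembly,
    initial_sM = cfg$initial_sM,
    controls = list(dt_s = ctl$dt, newton_tol = ctl$newton_tol,
                    newton_max_iter = ctl$newton_max_iter,
                    mobility_floor = ctl$mobility_floor,
                    max_halvings = ctl$max_halvings),
    assembly = lapply(cfg$assembly, function(s)
      list(radius_mm = s$radius * 1e3, length_mm = s$length * 1e3,
           name = if (is.null(s$name)) "" else s$name)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' @param path Path to a file written by [write_scenario_config()] (or
#'   hand-authored in the same layout).
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  l <- yaml::read_yaml(path)
  g <- l$geometry
  m <- l$medium
  ctl <- l$controls
  structure(list(
    name = l$name,
    geometry = list(type = g$type,
                    cyl_diameter = g$cyl_diameter_mm * 1e-3,
                    cyl_height = g$cyl_height_mm * 1e-3,
                    bore_radius = g$bore_radius_mm * 1e-3,
                    n_radial = as.integer(g$n_radial),
                    n_layers_half = as.integer(g$n_layers_half)),
    medium = medium_params(m$K_S_m2, m$porosity, m$lambda_bc,
                           m$R_char_mm * 1e-3, m$mu_lame_GPa * 1e9,
                           m$lambda_lame_GPa * 1e9),
    cement = .carreau_from_list(l$cement),
    marrow = .carreau_from_list(l$marrow),
    upscaling = upscaling_choice(l$upscaling),
    flow_rate = l$flow_rate_ml_per_s * 1e-6,
    injected_volume = l$injected_volume_ml * 1e-6,
    controls = solver_controls(dt = ctl$dt_s, newton_tol = ctl$newton_tol,
                               newton_max_iter = ctl$newton_max_iter,
                               mobility_floor = ctl$mobility_floor,
                               max_halvings = ctl$max_halvings),
    plunger_diameter = l$plunger_diameter_mm * 1e-3,
    assembly = lapply(l$assembly, function(s)
      tube_segment(s$radius_mm * 1e-3, s$length_mm * 1e-3,
                   if (identical(s$name, "")) NULL else s$name)),
    include_assembly = isTRUE(l$include_assembly),
    initial_sM = l$initial_sM), class = "scenario_config")
}
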