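# Tidy accessors and plots for run results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the time series of an injection run
#'
#' @param x An `injection_run`.
#' @param ... Unused.
#' @return The per-step time-series tibble: time \[s\], inlet pressure
#'   \[Pa\], injected and in-domain cement volumes \[m^3\], maximum solid
#'   displacement \[m\], bulk effective viscosities \[Pa s\], Newton
#'   iteration counts, and injection forces \[N\] (with and without the
#'   syringe-cannula assembly drop).
#' @exportS3Method generics::tidy
tidy.injection_run <- function(x, ...) x$timeseries

#' One-row summary of an injection run
#'
#' @param x An `injection_run`.
#' @param ... Unused.
#' @return A one-row tibble: final force and pressure, injected and
#'   in-domain cement volume, maximum displacement, bulk effective
#'   viscosities at the final step, assembly pressure drop, step count and
#'   Newton failures.
#' @exportS3Method generics::glance
glance.injection_run <- function(x, ...) {
  ts <- x$timeseries
  n <- nrow(ts)
  tibble::tibble(
    scenario = x$config$name,
    upscaling = x$config$upscaling$model,
    flow_rate_ml_s = x$config$flow_rate * 1e6,
    t_end = ts$time[n],
    force_end = ts$injection_force[n],
    force_foam_end = ts$injection_force_foam[n],
    inlet_pressure_end = ts$inlet_pressure[n],
    injected_volume_ml = ts$injected_volume[n] * 1e6,
    cement_volume_ml = ts$cement_volume[n] * 1e6,
    max_displacement = max(ts$max_displacement),
    bulk_visc_cement = ts$bulk_visc_cement[n],
    bulk_visc_marrow = ts$bulk_visc_marrow[n],
    assembly_dP = x$assembly_dP,
    n_steps = n,
    newton_failures = x$newton_failures)
}

#' Plot the injection-force history of a run
#'
#' @param object An `injection_run`.
#' @param foam_only Plot the foam-only force (without the assembly drop).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.injection_run <- function(object, foam_only = FALSE, ...) {
  ts <- object$timeseries
  ts$force <- if (foam_only) ts$injection_force_foam else ts$injection_force
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time [s]", y = "injection force [N]",
                  title = sprintf("%s scenario (%s upscaling)",
                                  object$config$name,
                                  object$config$upscaling$model)) +
    ggplot2::theme_minimal()
}

#' Plot a cement-saturation front profile
#'
#' @param object A `front_profile` tibble from [front_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.front_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance * 1e3, y = .data$sC)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "distance from injection point [mm]",
                  y = "cement saturation") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
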