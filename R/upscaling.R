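#' Choice of viscosity-upscaling model
#'
#' Selects how the pore-scale Carreau viscosity is mapped to the macro-scale
#' effective viscosity used in the Darcy equations. The two semi-empirical
#' capillary-bundle models share one effective-shear-rate formula and differ
#' only in the constant: Cannella uses C = 6.0, Hirasaki-Pope C = 0.69. The
#' third option computes the semi-analytical cross-section average viscosity
#' of flow through a representative pore channel of radius `R_char`.
#'
#' @param model One of `"cannella"`, `"hirasaki_pope"`, `"average_viscosity"`.
#' @param C_const Optional override of the semi-empirical constant.
#' @return An object of class `upscaling_choice`.
#' @export
upscaling_choice <- function(model = c("cannella", "hirasaki_pope",
                                       "average_viscosity"),
                             C_const = NULL) {
  model <- match.arg(model)
  if (is.null(C_const))
    C_const <- switch(model, cannella = 6.0, hirasaki_pope = 0.69,
                      average_viscosity = NA_real_)
  if (model != "average_viscosity" && !(C_const > 0))
    stop("C_const must be > 0 for the semi-empirical models", call. = FALSE)
  structure(list(model = model, C_const = C_const),
            class = "upscaling_choice")
}

#' Effective macro-scale shear rate (capillary-bundle models)
#'
#' \deqn{\dot\gamma_{eff} = \mathbb{C}\,
#'   \Big[\tfrac{3n+1}{4n}\Big]^{n/(n-1)}\,
#'   4\,|w_\beta|\sqrt{\tfrac{n^\beta}{8\,\kappa_r K^S}}.}
#' Zero at zero seepage velocity and linear in it. The relative permeability
#' is floored at `kr_floor` because the formula diverges as the phase becomes
#' immobile while its flux simultaneously vanishes.
#'
#' @param C_const Semi-empirical constant \[-\] (6.0 Cannella, 0.69
#'   Hirasaki-Pope).
#' @param n_rh Flow behaviour index \[-\] in (0, 1).
#' @param w_mag Seepage-velocity magnitude \[m/s\] (vectorized).
#' @param n_beta Phase volume fraction \[-\].
#' @param kr Relative permeability \[-\].
#' @param K_S Intrinsic permeability \[m^2\].
#' @param kr_floor Lower clamp for `kr` inside the formula.
#' @return Effective shear rate \[1/s\].
#' @export
effective_shear_rate <- function(C_const, n_rh, w_mag, n_beta, kr, K_S,
                                 kr_floor = 1e-6) {
  stopifnot(C_const > 0, n_rh > 0, n_rh < 1, K_S > 0)
  if (any(w_mag < 0) || any(n_beta < 0) || any(kr < 0))
    stop("w_mag, n_beta, kr must be >= 0", call. = FALSE)
  krc <- pmax(kr, kr_floor)
  shape <- ((3 * n_rh + 1) / (4 * n_rh))^(n_rh / (n_rh - 1))
  C_const * shape * 4 * w_mag * sqrt(n_beta / (8 * krc * K_S))
}

#' Semi-empirical effective viscosity (Cannella / Hirasaki-Pope)
#'
#' Plugs [effective_shear_rate()] into the Carreau law.
#'
#' @param choice An [upscaling_choice()] with a semi-empirical model.
#' @param params [carreau_params()] of the fluid.
#' @inheritParams effective_shear_rate
#' @return Effective viscosity \[Pa s\] in `[mu_inf, mu0]`; equals `mu0` at
#'   `w_mag = 0`.
#' @export
semi_empirical_viscosity <- function(choice, params, w_mag, n_beta, kr, K_S,
                                     kr_floor = 1e-6) {
  stopifnot(inherits(choice, "upscaling_choice"),
            choice$model %in% c("cannella", "hirasaki_pope"))
  if (params$n_rh == 1 || params$mu0 == params$mu_inf)
    return(rep(params$mu0, length(w_mag)))
  g <- effective_shear_rate(choice$C_const, params$n_rh, w_mag, n_beta, kr,
                            K_S, kr_floor)
  carreau_viscosity(params, g)
}

#' Semi-analytical average viscosity in a representative pore channel
#'
#' For a Carreau fluid driven through a tube of radius `R_char` at mean
#' velocity `v_mean`: (i) find the pressure gradient G such that laminar
#' generalized-Newtonian pipe flow has that mean velocity, then (ii) return
#' the cross-section area average of the local viscosity,
#' \deqn{\mu_{eff} = \frac{2}{R^2}\int_0^R \mu(\dot\gamma(r))\,r\,dr,}
#' where \eqn{\dot\gamma(r)} inverts \eqn{\tau(r) = G r/2}. Exact in the
#' Newtonian limit; `mu0` at zero flow.
#'
#' @param params [carreau_params()] of the fluid.
#' @param R_char Characteristic pore radius \[m\].
#' @param v_mean Mean pore velocity \[m/s\], >= 0 (vectorized).
#' @return Effective viscosity \[Pa s\] in `[mu_inf, mu0]`.
#' @export
average_viscosity <- function(params, R_char, v_mean) {
  stopifnot(inherits(params, "carreau_params"), R_char > 0)
  if (any(v_mean < 0)) stop("v_mean must be >= 0", call. = FALSE)
  if (params$mu0 == params$mu_inf || params$n_rh == 1)
    return(rep(params$mu0, length(v_mean)))
  vapply(v_mean, function(v) .average_viscosity_scalar(params, R_char, v),
         numeric(1))
}

.average_viscosity_scalar <- function(params, R, v) {
  if (v == 0) return(params$mu0)
  seg <- tube_segment(R, 1)          # unit length: dP == G
  Q <- v * pi * R^2
  G <- tube_pressure(params, seg, Q)
  tau_w <- G * R / 2
  # area average over the cross-section, via tau = G r / 2 substitution
  gl <- .gl_unit()
  r <- gl$x * R
  tau <- G * r / 2
  gam <- .carreau_shear_from_stress(params, tau)
  mu <- carreau_viscosity(params, gam)
  2 / R^2 * R * sum(gl$w * mu * r)
}

#' Effective viscosity of one fluid phase under a given upscaling model
#'
#' Dispatcher used by the solver for both fluids: routes to
#' [semi_empirical_viscosity()] or [average_viscosity()]. For the
#' average-viscosity model the representative-channel mean velocity is taken
#' as the seepage-velocity magnitude `w_mag`.
#'
#' @param choice An [upscaling_choice()].
#' @param params [carreau_params()] of the phase.
#' @param w_mag Seepage-velocity magnitude \[m/s\].
#' @param n_beta Phase volume fraction \[-\] (semi-empirical models).
#' @param kr Relative permeability \[-\] (semi-empirical models).
#' @param K_S Intrinsic permeability \[m^2\] (semi-empirical models).
#' @param R_char Characteristic pore radius \[m\] (average-viscosity model).
#' @param kr_floor Lower clamp for `kr` inside the effective shear rate.
#' @return Effective viscosity \[Pa s\].
#' @export
phase_effective_viscosity <- function(choice, params, w_mag, n_beta = NULL,
                                      kr = NULL, K_S = NULL, R_char = NULL,
                                      kr_floor = 1e-6) {
  stopifnot(inherits(choice, "upscaling_choice"))
  switch(choice$model,
    cannella = ,
    hirasaki_pope = semi_empirical_viscosity(choice, params, w_mag, n_beta,
                                             kr, K_S, kr_floor),
    average_viscosity = average_viscosity(params, R_char, w_mag),
    stop("unknown upscaling model", call. = FALSE))
}

# Build a fast vectorized closure mu(w_mag, n_beta, kr) for one phase, used
# inside the time-stepping loop. Semi-empirical models evaluate the closed
# form directly. The average-viscosity model is tabulated once on a log grid
# of mean velocities (it depends on w_mag only) and interpolated with a
# monotone Hermite spline; endpoints are exact plateaus.
.build_viscosity_fn <- function(choice, params, medium, kr_floor = 1e-6) {
  if (params$mu0 == params$mu_inf || params$n_rh == 1) {
    mu <- params$mu0
    return(function(w_mag, n_beta, kr) rep(mu, length(w_mag)))
  }
  if (choice$model %in% c("cannella", "hirasaki_pope")) {
    force(choice); force(params); force(medium)
    return(function(w_mag, n_beta, kr)
      semi_empirical_viscosity(choice, params, w_mag, n_beta, kr,
                               medium$K_S, kr_floor))
  }
  # average-viscosity model: log-grid interpolant in w_mag
  v_grid <- 10^seq(-12, 1, length.out = 160)
  mu_grid <- average_viscosity(params, medium$R_char, v_grid)
  sp <- stats::splinefun(log(v_grid), log(mu_grid), method = "monoH.FC")
  mu0 <- params$mu0; mu_inf <- params$mu_inf
  function(w_mag, n_beta, kr) {
    out <- rep(mu0, length(w_mag))
    hi <- w_mag > 10
    lo <- w_mag > 1e-12 & !hi
    if (any(hi)) out[hi] <- average_viscosity(params, medium$R_char, w_mag[hi])
    if (any(lo)) out[lo] <- exp(sp(log(w_mag[lo])))
    pmin(pmax(out, mu_inf), mu0)
  }
}
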