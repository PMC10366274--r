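#' Carreau rheology parameters for one pore fluid
#'
#' Bundles the four parameters of the Carreau shear-thinning law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
#'   [1 + (\lambda_{rh}\dot\gamma)^2]^{(n_{rh}-1)/2}.}
#' A Newtonian fluid is the special case `mu0 == mu_inf` (or `n_rh = 1`);
#' the convenience wrapper [newtonian_params()] builds that directly.
#'
#' @param mu0 Zero-shear viscosity limit \[Pa s\].
#' @param mu_inf Infinite-shear viscosity limit \[Pa s\], `0 < mu_inf <= mu0`.
#' @param lambda_rh Relaxation time \[s\]: reciprocal of the shear rate where
#'   shear thinning sets in. Non-negative.
#' @param n_rh Flow behaviour index \[-\], in (0, 1].
#' @return An object of class `carreau_params`.
#' @export
#' @examples
#' cem <- carreau_params(1930, 1.93, 1.38, 0.30)
#' carreau_viscosity(cem, c(0, 1, 100))
carreau_params <- function(mu0, mu_inf, lambda_rh = 0, n_rh = 1) {
  stopifnot(is.numeric(mu0), is.numeric(mu_inf),
            is.numeric(lambda_rh), is.numeric(n_rh),
            length(mu0) == 1, length(mu_inf) == 1,
            length(lambda_rh) == 1, length(n_rh) == 1)
  if (!(mu_inf > 0) || !(mu0 >= mu_inf))
    stop("carreau_params: need mu0 >= mu_inf > 0", call. = FALSE)
  if (lambda_rh < 0) stop("carreau_params: lambda_rh must be >= 0", call. = FALSE)
  if (!(n_rh > 0 && n_rh <= 1))
    stop("carreau_params: n_rh must lie in (0, 1]", call. = FALSE)
  structure(list(mu0 = mu0, mu_inf = mu_inf,
                 lambda_rh = lambda_rh, n_rh = n_rh),
            class = "carreau_params")
}

#' @rdname carreau_params
#' @param mu Constant viscosity \[Pa s\] of a Newtonian fluid.
#' @export
newtonian_params <- function(mu) carreau_params(mu, mu, 0, 1)

#' @export
print.carreau_params <- function(x, ...) {
  if (x$mu0 == x$mu_inf) {
    cat(sprintf("<carreau_params> Newtonian, mu = %g Pa s\n", x$mu0))
  } else {
    cat(sprintf(
      "<carreau_params> mu0 = %g, mu_inf = %g Pa s, lambda_rh = %g s, n_rh = %g\n",
      x$mu0, x$mu_inf, x$lambda_rh, x$n_rh))
  }
  invisible(x)
}

#' Transport and elasticity parameters of the porous skeleton
#'
#' Intrinsic (pore-geometry) transport properties plus the Hookean elastic
#' constants of the solid skeleton. The initial solid volume fraction is
#' `nS_0S = 1 - n_F` (fully saturated medium, no voids).
#'
#' @param K_S Intrinsic permeability \[m^2\], scalar (isotropic).
#' @param n_F Porosity \[-\], in (0, 1).
#' @param lambda_bc Brooks-Corey pore-size uniformity parameter \[-\], > 0.
#' @param R_char Characteristic pore radius \[m\] used by the
#'   average-viscosity upscaling model.
#' @param mu_lame,lambda_lame Lame parameters of the skeleton \[Pa\].
#' @return An object of class `medium_params`.
#' @export
medium_params <- function(K_S, n_F, lambda_bc, R_char, mu_lame, lambda_lame) {
  stopifnot(K_S > 0, n_F > 0, n_F < 1, lambda_bc > 0, R_char > 0,
            mu_lame > 0)
  structure(list(K_S = K_S, n_F = n_F, lambda_bc = lambda_bc,
                 R_char = R_char, mu_lame = mu_lame,
                 lambda_lame = lambda_lame, nS_0S = 1 - n_F),
            class = "medium_params")
}

#' @export
print.medium_params <- function(x, ...) {
  cat(sprintf(
    "<medium_params> K_S = %g m^2, n_F = %g, lambda_bc = %g, R_char = %g m\n",
    x$K_S, x$n_F, x$lambda_bc, x$R_char))
  cat(sprintf("  Lame: mu = %g Pa, lambda = %g Pa, nS_0S = %g\n",
              x$mu_lame, x$lambda_lame, x$nS_0S))
  invisible(x)
}

#' Carreau viscosity at a given shear rate
#'
#' @param params A [carreau_params()] object.
#' @param gamma_dot Shear rate(s) \[1/s\], non-negative (vectorized).
#' @return Viscosity \[Pa s\], bounded in `[mu_inf, mu0]`, non-increasing in
#'   `gamma_dot`.
#' @export
carreau_viscosity <- function(params, gamma_dot) {
  stopifnot(inherits(params, "carreau_params"))
  if (any(gamma_dot < 0)) stop("gamma_dot must be >= 0", call. = FALSE)
  if (params$n_rh == 1 || params$mu0 == params$mu_inf)
    return(rep(params$mu0, length(gamma_dot)))
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lambda_rh * gamma_dot)^2)^((params$n_rh - 1) / 2)
}

#' Brooks-Corey relative permeabilities
#'
#' Relative permeability of the cement (non-wetting displacement front) and
#' the marrow phase as a function of the marrow saturation:
#' \deqn{\kappa_r^C = (1-s^M)^2 [1 - (s^M)^{(2+\lambda_{bc})/\lambda_{bc}}],
#'   \quad \kappa_r^M = (s^M)^{(2+3\lambda_{bc})/\lambda_{bc}}.}
#'
#' @param lambda_bc Uniformity parameter \[-\], > 0.
#' @param sM Marrow saturation(s) in \[0, 1\] (vectorized).
#' @return A list with components `kr_C` and `kr_M`, both in \[0, 1\].
#' @export
brooks_corey <- function(lambda_bc, sM) {
  stopifnot(lambda_bc > 0)
  if (any(sM < 0 | sM > 1)) stop("sM must lie in [0, 1]", call. = FALSE)
  kr_C <- (1 - sM)^2 * (1 - sM^((2 + lambda_bc) / lambda_bc))
  kr_M <- sM^((2 + 3 * lambda_bc) / lambda_bc)
  list(kr_C = pmin(pmax(kr_C, 0), 1), kr_M = pmin(pmax(kr_M, 0), 1))
}

#' Linear Hookean solid extra stress
#'
#' \eqn{\sigma_E^S = 2\mu\,\epsilon + \lambda\,\mathrm{tr}(\epsilon)\,I} for a
#' symmetric small-strain tensor.
#'
#' @param mu_lame,lambda_lame Lame parameters \[Pa\].
#' @param strain Symmetric 3x3 strain tensor \[-\].
#' @return Symmetric 3x3 stress tensor \[Pa\].
#' @export
hooke_stress <- function(mu_lame, lambda_lame, strain) {
  strain <- as.matrix(strain)
  stopifnot(all(dim(strain) == c(3, 3)))
  if (max(abs(strain - t(strain))) > 1e-12 * max(1, max(abs(strain))))
    stop("strain tensor must be symmetric", call. = FALSE)
  2 * mu_lame * strain + lambda_lame * sum(diag(strain)) * diag(3)
}

#' Solid volume fraction under small-strain dilatation
#'
#' Linearized form of the solid volume balance
#' \eqn{n^S = n^S_{0S}\,(\det F_S)^{-1}}: with small-strain kinematics
#' \eqn{\det F_S \approx 1 + \mathrm{div}\,u_S}, so
#' \eqn{n^S = n^S_{0S} / (1 + \mathrm{div}\,u_S)}.
#'
#' @param nS_0S Initial solid volume fraction \[-\].
#' @param div_u Solid dilatation \eqn{\mathrm{div}\,u_S} \[-\] (vectorized),
#'   must exceed -1.
#' @return Current solid volume fraction \[-\].
#' @export
solid_volume_fraction <- function(nS_0S, div_u) {
  if (any(div_u <= -1))
    stop("degenerate compression: div_u must be > -1", call. = FALSE)
  nS_0S / (1 + div_u)
}

#' Volume fractions and saturations of the three-phase mixture
#'
#' Splits the pore space `1 - nS` between cement and marrow according to the
#' marrow saturation, enforcing the saturation conditions
#' \eqn{n^S + n^C + n^M = 1} and \eqn{s^C + s^M = 1}.
#'
#' @param nS Solid volume fraction \[-\], in (0, 1).
#' @param sM Marrow saturation \[-\], in \[0, 1\].
#' @return A list of class `phase_fractions` with `nS`, `nC`, `nM`, `sC`, `sM`.
#' @export
phase_fractions <- function(nS, sM) {
  if (any(nS <= 0 | nS >= 1)) stop("nS must lie in (0, 1)", call. = FALSE)
  if (any(sM < 0 | sM > 1)) stop("sM must lie in [0, 1]", call. = FALSE)
  sC <- 1 - sM
  nF <- 1 - nS
  structure(list(nS = nS, nC = nF * sC, nM = nF * sM, sC = sC, sM = sM),
            class = "phase_fractions")
}
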