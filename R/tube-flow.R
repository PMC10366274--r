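#' A straight tube segment of the injection assembly
#'
#' @param radius Inner radius \[m\], > 0.
#' @param length Length \[m\], > 0.
#' @param name Optional label (e.g. "syringe", "cannula").
#' @return An object of class `tube_segment`.
#' @export
tube_segment <- function(radius, length, name = NULL) {
  stopifnot(radius > 0, length > 0)
  structure(list(radius = radius, length = length, name = name),
            class = "tube_segment")
}

#' Default syringe-nozzle-cannula assembly
#'
#' Geometry of a typical 2-ml vertebroplasty syringe assembly: barrel of
#' inner diameter 9.7 mm, a short taper-equivalent nozzle, and a cannula of
#' inner diameter 3.2 mm and length 100 mm. All dimensions are overridable by
#' constructing the list of [tube_segment()]s directly.
#'
#' @return A list of three `tube_segment` objects.
#' @export
default_assembly_segments <- function() {
  list(tube_segment(9.7e-3 / 2, 60e-3, "syringe"),
       tube_segment(2.0e-3, 10e-3, "nozzle"),
       tube_segment(3.2e-3 / 2, 100e-3, "cannula"))
}

# Gauss-Legendre nodes on [0, 1], computed once and rescaled per call
.gl_unit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(80, 0, 1)
    cache
  }
})

# invert tau = mu(gamma) * gamma for a Carreau fluid (strictly increasing
# for n_rh <= 1) by vectorized bisection in log gamma; the root is bracketed
# by tau/mu0 and tau/mu_inf since mu lies between the plateaus
.carreau_shear_from_stress <- function(params, tau) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (params$mu0 == params$mu_inf || params$n_rh == 1) {
    out[pos] <- tau[pos] / params$mu0
    return(out)
  }
  tv <- tau[pos]
  lo <- log(tv / params$mu0)
  hi <- log(tv / params$mu_inf)
  for (k in 1:55) {
    mid <- 0.5 * (lo + hi)
    g <- exp(mid)
    too_big <- carreau_viscosity(params, g) * g > tv
    hi[too_big] <- mid[too_big]
    lo[!too_big] <- mid[!too_big]
  }
  out[pos] <- exp(0.5 * (lo + hi))
  out
}

#' Volumetric flow rate of a Carreau fluid through a tube
#'
#' Shear-stress formulation of fully developed laminar generalized-Newtonian
#' pipe flow: with wall shear stress \eqn{\tau_w = \Delta p\,R/(2L)},
#' \deqn{Q = \frac{\pi R^3}{\tau_w^3}\int_0^{\tau_w} \tau^2\,
#'   \dot\gamma(\tau)\,d\tau,}
#' where \eqn{\dot\gamma(\tau)} inverts the monotone map
#' \eqn{\tau = \mu(\dot\gamma)\dot\gamma}. Recovers Hagen-Poiseuille exactly
#' in the Newtonian limit.
#'
#' @param params A [carreau_params()] object.
#' @param seg A [tube_segment()].
#' @param dP Driving pressure drop \[Pa\], >= 0.
#' @return Flow rate \[m^3/s\], strictly increasing in `dP`.
#' @export
tube_flowrate <- function(params, seg, dP) {
  stopifnot(inherits(params, "carreau_params"), inherits(seg, "tube_segment"))
  if (dP < 0) stop("dP must be >= 0", call. = FALSE)
  if (dP == 0) return(0)
  R <- seg$radius
  tau_w <- dP * R / (2 * seg$length)
  if (params$mu0 == params$mu_inf || params$n_rh == 1)
    return(pi * R^4 * dP / (8 * params$mu0 * seg$length))
  # Gauss-Legendre on [0, tau_w]; integrand tau^2 * gamma(tau) is smooth and
  # monotone, 80 nodes give ~1e-12 relative accuracy over the Carreau family.
  gl <- .gl_unit()
  x <- gl$x * tau_w
  gam <- .carreau_shear_from_stress(params, x)
  I <- tau_w * sum(gl$w * x^2 * gam)
  pi * R^3 / tau_w^3 * I
}

#' Pressure drop required to drive a given flow rate through a tube
#'
#' Monotone inversion of [tube_flowrate()].
#'
#' @inheritParams tube_flowrate
#' @param Q Flow rate \[m^3/s\], >= 0.
#' @return Pressure drop \[Pa\].
#' @export
tube_pressure <- function(params, seg, Q) {
  stopifnot(inherits(params, "carreau_params"), inherits(seg, "tube_segment"))
  if (Q < 0) stop("Q must be >= 0", call. = FALSE)
  if (Q == 0) return(0)
  R <- seg$radius
  if (params$mu0 == params$mu_inf || params$n_rh == 1)
    return(8 * params$mu0 * seg$length * Q / (pi * R^4))
  # viscosity between the plateaus brackets dP by the Newtonian formulas;
  # Q(dP) is near power-law, so regula falsi on log-log converges fast
  lo <- log(8 * params$mu_inf * seg$length * Q / (pi * R^4)) - 1e-9
  hi <- log(8 * params$mu0 * seg$length * Q / (pi * R^4)) + 1e-9
  lQ <- log(Q)
  flo <- log(tube_flowrate(params, seg, exp(lo))) - lQ
  fhi <- log(tube_flowrate(params, seg, exp(hi))) - lQ
  side <- 0L
  for (k in 1:100) {
    mid <- hi - fhi * (hi - lo) / (fhi - flo)
    mid <- min(max(mid, lo + 1e-15), hi - 1e-15)
    fmid <- log(tube_flowrate(params, seg, exp(mid))) - lQ
    if (abs(fmid) < 1e-13) return(exp(mid))
    if (fmid > 0) {
      hi <- mid; fhi <- fmid
      if (side == 1L) flo <- flo / 2   # Illinois anti-stagnation
      side <- 1L
    } else {
      lo <- mid; flo <- fmid
      if (side == -1L) fhi <- fhi / 2
      side <- -1L
    }
    if (hi - lo < 1e-13) break
  }
  exp(0.5 * (lo + hi))
}

#' Pressure drop across tube segments in series
#'
#' Sum of [tube_pressure()] over segments at equal flow rate (series flow,
#' entrance and exit effects neglected).
#'
#' @inheritParams tube_pressure
#' @param segments Non-empty list of [tube_segment()] objects.
#' @return Total pressure drop \[Pa\].
#' @export
assembly_pressure <- function(params, segments, Q) {
  if (length(segments) == 0) stop("empty segment list", call. = FALSE)
  sum(vapply(segments, function(s) tube_pressure(params, s, Q), numeric(1)))
}

#' Identify Carreau exponents from two injection observations
#'
#' Given two (flow rate, driving pressure) pairs measured on the
#' syringe-nozzle-cannula assembly without the porous medium, and the two
#' viscosity plateaus, solves for the relaxation time and flow behaviour
#' index such that [assembly_pressure()] reproduces both observations.
#' Solved as damped Newton iterations on log(lambda_rh) and logit(n_rh) from
#' multiple starting points.
#'
#' @param obs1,obs2 Lists with components `flow_rate` \[m^3/s\] and
#'   `pressure` \[Pa\]; the two flow rates must differ.
#' @param mu0,mu_inf Viscosity plateaus \[Pa s\], `mu0 > mu_inf`.
#' @param segments List of [tube_segment()]s (default: [default_assembly_segments()]).
#' @param rel_tol Relative pressure-residual tolerance for acceptance.
#' @return A list with `lambda_rh`, `n_rh`, `residuals` (relative pressure
#'   errors at the two observations), and `boundary` (`TRUE` if the fit ran
#'   into the Newtonian limit `n_rh -> 1`, e.g. for data with pressures
#'   exactly proportional to flow rate).
#' @export
fit_carreau_exponents <- function(obs1, obs2, mu0, mu_inf,
                                  segments = default_assembly_segments(),
                                  rel_tol = 1e-6) {
  stopifnot(obs1$flow_rate > 0, obs2$flow_rate > 0,
            obs1$pressure > 0, obs2$pressure > 0, mu0 > mu_inf)
  if (obs1$flow_rate == obs2$flow_rate)
    stop("the two observations must have distinct flow rates", call. = FALSE)

  resid <- function(th) {
    lam <- exp(th[1])
    n <- 1 / (1 + exp(-th[2]))
    p <- carreau_params(mu0, mu_inf, lam, n)
    c(assembly_pressure(p, segments, obs1$flow_rate) / obs1$pressure - 1,
      assembly_pressure(p, segments, obs2$flow_rate) / obs2$pressure - 1)
  }

  starts <- list(c(log(1), 0), c(log(0.1), -1), c(log(10), 1),
                 c(log(1), -2), c(log(0.01), 0.5))
  best <- NULL
  for (th0 in starts) {
    if (!is.null(best) && best$ss < (rel_tol * 0.1)^2) break
    th <- th0
    ok <- TRUE
    for (it in 1:60) {
      r <- tryCatch(resid(th), error = function(e) NULL)
      if (is.null(r) || any(!is.finite(r))) { ok <- FALSE; break }
      if (max(abs(r)) < rel_tol * 0.1) break
      # finite-difference Jacobian (2x2)
      h <- 1e-6
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        tp <- th; tp[j] <- tp[j] + h
        rp <- tryCatch(resid(tp), error = function(e) NULL)
        if (is.null(rp)) { ok <- FALSE; break }
        J[, j] <- (rp - r) / h
      }
      if (!ok) break
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      # damping with logit bound control
      alpha <- 1
      repeat {
        thn <- th + alpha * step
        if (thn[2] > 30) thn[2] <- 30
        rn <- tryCatch(resid(thn), error = function(e) NULL)
        if (!is.null(rn) && all(is.finite(rn)) &&
            (sum(rn^2) < sum(r^2) || alpha < 1e-3)) break
        alpha <- alpha / 2
      }
      th <- thn
    }
    r <- tryCatch(resid(th), error = function(e) c(Inf, Inf))
    if (ok && all(is.finite(r))) {
      if (is.null(best) || sum(r^2) < best$ss)
        best <- list(th = th, r = r, ss = sum(r^2))
    }
  }
  if (is.null(best))
    stop("fit_carreau_exponents: no solution found", call. = FALSE)
  lam <- exp(best$th[1])
  n <- 1 / (1 + exp(-best$th[2]))
  # Newtonian-limit diagnostic: either n_rh at its upper boundary, or the
  # fitted member predicts pressures indistinguishable from the zero-shear
  # plateau over the observed flow rates (lambda_rh effectively zero)
  fitted <- carreau_params(mu0, mu_inf, lam, min(n, 1))
  p_newt <- vapply(list(obs1, obs2), function(o)
    assembly_pressure(newtonian_params(mu0), segments, o$flow_rate),
    numeric(1))
  p_fit <- vapply(list(obs1, obs2), function(o)
    assembly_pressure(fitted, segments, o$flow_rate), numeric(1))
  boundary <- n > 1 - 1e-4 || max(abs(p_fit / p_newt - 1)) < 1e-3
  if (max(abs(best$r)) > rel_tol && !boundary)
    stop(sprintf(paste0("fit_carreau_exponents: residuals (%.3e, %.3e) ",
                        "exceed tolerance %.1e"),
                 best$r[1], best$r[2], rel_tol), call. = FALSE)
  list(lambda_rh = lam, n_rh = n, residuals = best$r, boundary = boundary)
}
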