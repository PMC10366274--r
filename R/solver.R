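# Monolithic implicit solver for the coupled solid-cement-marrow system:
# Bubnov-Galerkin FE for the solid momentum balance, vertex-centered Box FV
# with fully-upwind mobilities and mass-lumped storage for the two fluid
# volume balances, implicit Euler in time, Newton linearization with the
# effective viscosity resolved locally at each sub-control-volume face.
#
# Per-vertex unknown ordering (interleaved): ux, uy, uz, p, sM.

#' Solver controls
#'
#' @param dt Time-step size \[s\].
#' @param newton_tol Relative residual tolerance (per equation block,
#'   against the first-iterate residual of the step).
#' @param newton_max_iter Maximum Newton iterations per step.
#' @param mobility_floor Relative-permeability floor used inside the
#'   effective-shear-rate formula of the upscaling models.
#' @param max_halvings Maximum number of dt halvings after a failed step.
#' @return An object of class `solver_controls`.
#' @export
solver_controls <- function(dt = 0.25, newton_tol = 1e-8,
                            newton_max_iter = 30, mobility_floor = 1e-6,
                            max_halvings = 5) {
  stopifnot(dt > 0, newton_tol > 0, newton_max_iter >= 1)
  structure(list(dt = dt, newton_tol = newton_tol,
                 newton_max_iter = newton_max_iter,
                 mobility_floor = mobility_floor,
                 max_halvings = max_halvings),
            class = "solver_controls")
}

#' Boundary conditions by facet tag
#'
#' @param dirichlet_p Named numeric: tag -> prescribed pore pressure \[Pa\].
#' @param dirichlet_sM Named numeric: tag -> prescribed marrow saturation.
#' @param dirichlet_u_tags Tags whose vertices are clamped (u = 0); the
#'   special value `"all"` clamps every vertex (rigid-skeleton runs).
#' @param extra_u_fixed Additional vertex ids to clamp (e.g. a support face
#'   selected geometrically, to remove rigid-body modes).
#' @param inflow Named numeric: tag -> total injected cement volumetric rate
#'   Q \[m^3/s\]; the prescribed normal flux is Q divided by the summed
#'   tagged facet area.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(dirichlet_p = numeric(),
                                dirichlet_sM = numeric(),
                                dirichlet_u_tags = character(),
                                extra_u_fixed = integer(),
                                inflow = numeric()) {
  structure(list(dirichlet_p = dirichlet_p, dirichlet_sM = dirichlet_sM,
                 dirichlet_u_tags = dirichlet_u_tags,
                 extra_u_fixed = extra_u_fixed, inflow = inflow),
            class = "boundary_conditions")
}

#' Darcy volumetric phase flux
#'
#' \eqn{n^\beta w_\beta = -(\kappa_r K^S / \mu_{eff})\,\mathrm{grad}\,p}.
#'
#' @param p_gradient Pressure gradient \[Pa/m\], length-3 vector or
#'   `n x 3` matrix.
#' @param kr Relative permeability \[-\].
#' @param K_S Intrinsic permeability \[m^2\].
#' @param mu_eff Effective dynamic viscosity \[Pa s\], > 0.
#' @return Volumetric phase flux \[m/s\], same shape as `p_gradient`.
#' @export
darcy_phase_flux <- function(p_gradient, kr, K_S, mu_eff) {
  stopifnot(all(mu_eff > 0))
  -(kr * K_S / mu_eff) * p_gradient
}

.idx_u <- function(v, comp) (v - 1L) * 5L + comp
.idx_p <- function(v) (v - 1L) * 5L + 4L
.idx_s <- function(v) (v - 1L) * 5L + 5L

#' Initial mixture state
#'
#' @param topo A `box_topology`.
#' @param sM Initial marrow saturation (scalar or per-vertex).
#' @param p Initial pore pressure \[Pa\].
#' @param t Time \[s\].
#' @return An object of class `mixture_state` with per-vertex displacement,
#'   pressure and marrow saturation.
#' @export
mixture_state <- function(topo, sM = 1, p = 0, t = 0) {
  nv <- topo$nv
  structure(list(u = matrix(0, nv, 3), p = rep(p, length.out = nv),
                 sM = rep(sM, length.out = nv), t = t),
            class = "mixture_state")
}

.vertices_with_tag <- function(mesh, tags) {
  b <- mesh$boundary
  sel <- b$tag %in% tags
  sort(unique(c(b$v1[sel], b$v2[sel], b$v3[sel], b$v4[sel])))
}

#' Build the assembled injection system
#'
#' Precomputes everything the Newton solver needs: the constant solid
#' stiffness and pressure-coupling matrices, fluid-block scatter indices,
#' resolved Dirichlet sets, inflow source vector (prescribed flux = Q over
#' summed tagged facet area), and fast per-phase effective-viscosity
#' closures for the chosen upscaling model.
#'
#' @param topo A `box_topology`.
#' @param medium A [medium_params()].
#' @param cement,marrow [carreau_params()] of the two pore fluids.
#' @param choice An [upscaling_choice()].
#' @param bcs A [boundary_conditions()].
#' @param controls A [solver_controls()].
#' @return An object of class `injection_system`.
#' @export
build_injection_system <- function(topo, medium, cement, marrow, choice,
                                   bcs, controls = solver_controls()) {
  stopifnot(inherits(topo, "box_topology"), inherits(medium, "medium_params"),
            inherits(cement, "carreau_params"),
            inherits(marrow, "carreau_params"),
            inherits(choice, "upscaling_choice"),
            inherits(bcs, "boundary_conditions"))
  mesh <- topo$mesh
  nv <- topo$nv
  nc <- topo$nc
  ndof <- 5L * nv
  cells <- mesh$cells

  # fast-access fluid assembly arrays
  gN <- lapply(1:12, function(e) lapply(1:3, function(k)
    matrix(topo$scvf_gradN[, e, , k], nc, 8)))
  nvec <- lapply(1:12, function(e) lapply(1:3, function(k) topo$scvf_n[, e, k]))
  g0 <- lapply(1:3, function(k) matrix(topo$gradN0[, , k], nc, 8))

  # Dirichlet resolution
  dir_dofs <- integer(0); dir_vals <- numeric(0)
  for (tag in names(bcs$dirichlet_p)) {
    v <- .vertices_with_tag(mesh, tag)
    dir_dofs <- c(dir_dofs, .idx_p(v))
    dir_vals <- c(dir_vals, rep(bcs$dirichlet_p[[tag]], length(v)))
  }
  for (tag in names(bcs$dirichlet_sM)) {
    v <- .vertices_with_tag(mesh, tag)
    dir_dofs <- c(dir_dofs, .idx_s(v))
    dir_vals <- c(dir_vals, rep(bcs$dirichlet_sM[[tag]], length(v)))
  }
  uv <- if (identical(bcs$dirichlet_u_tags, "all")) seq_len(nv) else
    union(.vertices_with_tag(mesh, bcs$dirichlet_u_tags), bcs$extra_u_fixed)
  for (comp in 1:3) {
    dir_dofs <- c(dir_dofs, .idx_u(uv, comp))
    dir_vals <- c(dir_vals, rep(0, length(uv)))
  }
  keep <- !duplicated(dir_dofs)
  dir_dofs <- dir_dofs[keep]; dir_vals <- dir_vals[keep]
  if (length(uv) == 0)
    warning("no displacement constraints: solid block is singular")

  # inflow source over the cement-balance rows (and inlet vertex set)
  b_in <- numeric(ndof)
  inflow_vertices <- integer(0)
  inflow_area <- 0
  Q_total <- 0
  for (tag in names(bcs$inflow)) {
    sel <- mesh$boundary$tag == tag
    if (!any(sel)) stop(sprintf("empty inflow tag '%s'", tag), call. = FALSE)
    sub <- topo$bnd_subarea[sel, , drop = FALSE]
    vids <- as.matrix(mesh$boundary[sel, paste0("v", 1:4)])
    A <- sum(sub)
    q_n <- bcs$inflow[[tag]] / A
    acc <- rowsum(as.vector(sub) * q_n, as.vector(vids))
    b_in[.idx_p(as.integer(rownames(acc)))] <-
      b_in[.idx_p(as.integer(rownames(acc)))] + acc[, 1]
    inflow_vertices <- union(inflow_vertices, unique(as.vector(vids)))
    inflow_area <- inflow_area + A
    Q_total <- Q_total + bcs$inflow[[tag]]
  }

  # constant momentum block: R_u = K_uu u + C_up p (Dirichlet rows masked in)
  Xc <- .cell_coord_list(mesh)
  gp_pts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * .gauss2
  EK <- vector("list", 64)        # per (a,b): nc x 9 accumulators (i,j)
  EC <- vector("list", 64)        # per (a,b): nc x 3 accumulators (i)
  for (ab in 1:64) { EK[[ab]] <- matrix(0, nc, 9); EC[[ab]] <- matrix(0, nc, 3) }
  mu_l <- medium$mu_lame; la_l <- medium$lambda_lame
  for (g in seq_len(nrow(gp_pts))) {
    geo <- .hex_geom_at(Xc, gp_pts[g, ])
    w <- geo$detJ                       # unit gauss weights
    Ng <- geo$N
    for (a in 1:8) for (b in 1:8) {
      ab <- (a - 1) * 8 + b
      dot_ab <- geo$gradN[, a, 1] * geo$gradN[, b, 1] +
                geo$gradN[, a, 2] * geo$gradN[, b, 2] +
                geo$gradN[, a, 3] * geo$gradN[, b, 3]
      for (i in 1:3) for (j in 1:3) {
        val <- mu_l * ((i == j) * dot_ab +
                       geo$gradN[, b, i] * geo$gradN[, a, j]) +
               la_l * geo$gradN[, a, i] * geo$gradN[, b, j]
        EK[[ab]][, (i - 1) * 3 + j] <- EK[[ab]][, (i - 1) * 3 + j] + w * val
      }
      for (i in 1:3)
        EC[[ab]][, i] <- EC[[ab]][, i] + w * Ng[a] * geo$gradN[, b, i]
    }
  }
  iK <- jK <- integer(0); xK <- numeric(0)
  iC <- jC <- integer(0); xC <- numeric(0)
  iK_l <- vector("list", 64 * 9); jK_l <- iK_l; xK_l <- iK_l
  iC_l <- vector("list", 64 * 3); jC_l <- iC_l; xC_l <- iC_l
  nK <- 0; nCt <- 0
  for (a in 1:8) for (b in 1:8) {
    ab <- (a - 1) * 8 + b
    va <- cells[, a]; vb <- cells[, b]
    for (i in 1:3) for (j in 1:3) {
      nK <- nK + 1
      iK_l[[nK]] <- .idx_u(va, i); jK_l[[nK]] <- .idx_u(vb, j)
      xK_l[[nK]] <- EK[[ab]][, (i - 1) * 3 + j]
    }
    for (i in 1:3) {
      nCt <- nCt + 1
      iC_l[[nCt]] <- .idx_u(va, i); jC_l[[nCt]] <- .idx_p(vb)
      xC_l[[nCt]] <- EC[[ab]][, i]
    }
  }
  Amom <- Matrix::sparseMatrix(
    i = c(unlist(iK_l), unlist(iC_l)),
    j = c(unlist(jK_l), unlist(jC_l)),
    x = c(unlist(xK_l), unlist(xC_l)), dims = c(ndof, ndof))

  # fluid Jacobian scatter indices in compact fluid numbering
  # (p at vertex v -> row v, sM -> row nv + v); 16 local rows/cols per cell
  loc_dof <- cbind(cells, nv + cells)               # nc x 16
  iF <- array(0L, c(nc, 16, 16)); jF <- array(0L, c(nc, 16, 16))
  for (col in 1:16) iF[, , col] <- loc_dof
  for (r in 1:16) jF[, r, ] <- loc_dof
  # u-coupling block: fluid rows x u cols (compact u numbering (v-1)*3+comp)
  u_dof <- cbind((cells - 1L) * 3L + 1L, (cells - 1L) * 3L + 2L,
                 (cells - 1L) * 3L + 3L)
  iB <- array(0L, c(nc, 16, 24)); jB <- array(0L, c(nc, 16, 24))
  for (col in 1:24) iB[, , col] <- loc_dof
  for (r in 1:16) jB[, r, ] <- u_dof

  free_mask <- rep(1, ndof); free_mask[dir_dofs] <- 0
  Dfree <- Matrix::Diagonal(x = free_mask)
  Ddir <- Matrix::Diagonal(x = 1 - free_mask)

  # index maps between interleaved 5nv numbering and the compact blocks
  vseq <- seq_len(nv)
  udofs5 <- as.vector(t(cbind(.idx_u(vseq, 1), .idx_u(vseq, 2),
                              .idx_u(vseq, 3))))   # compact (v-1)*3+comp order
  fdofs5 <- c(.idx_p(vseq), .idx_s(vseq))          # compact p then sM order
  # fluid Dirichlet rows in compact numbering
  dir_is_p <- (dir_dofs - 1L) %% 5L + 1L == 4L
  dir_is_s <- (dir_dofs - 1L) %% 5L + 1L == 5L
  dirF2 <- c((dir_dofs[dir_is_p] - 4L) %/% 5L + 1L,
             nv + (dir_dofs[dir_is_s] - 5L) %/% 5L + 1L)
  freeF <- rep(1, 2L * nv); freeF[dirF2] <- 0
  # constant momentum sub-blocks in compact numbering, Dirichlet rows masked
  Amom_masked <- Dfree %*% Amom + Ddir
  Auu <- Amom_masked[udofs5, udofs5]
  Cup <- (Dfree %*% Amom)[udofs5, .idx_p(vseq)]
  rsU <- pmax(Matrix::rowSums(abs(Auu)), 1e-300)
  DrU <- Matrix::Diagonal(x = 1 / rsU)
  luU <- Matrix::lu(DrU %*% Auu)

  # interior-vertex mask for bulk diagnostics: exclude boundary vertices and
  # their cell neighbours
  bnd_v <- .vertices_with_tag(mesh, unique(mesh$boundary$tag))
  touch <- rowSums(matrix(cells %in% bnd_v, nc, 8)) > 0
  near_bnd <- unique(as.vector(cells[touch, ]))
  interior_mask <- !(seq_len(nv) %in% union(bnd_v, near_bnd))

  absAmom <- abs(Amom)
  sys <- list(topo = topo, mesh = mesh, medium = medium, cement = cement,
              marrow = marrow, choice = choice, bcs = bcs,
              controls = controls, nv = nv, nc = nc, ndof = ndof,
              cells = cells, gN = gN, nvec = nvec, g0 = g0,
              scv_vol = topo$scv_vol,
              Amom = Amom, absAmom = absAmom, b_in = b_in,
              dir_dofs = dir_dofs,
              dir_vals = dir_vals, Dfree = Dfree, Ddir = Ddir,
              free_mask = free_mask,
              iF = as.vector(iF), jF = as.vector(jF),
              iB = as.vector(iB), jB = as.vector(jB),
              udofs5 = udofs5, fdofs5 = fdofs5, dirF2 = dirF2,
              freeF = freeF, Auu = Auu, Cup = Cup, DrU = DrU, luU = luU,
              inflow_vertices = inflow_vertices, inflow_area = inflow_area,
              Q_total = Q_total,
              vert_vol = vertex_volumes(topo),
              interior_mask = interior_mask,
              visc_C = .build_viscosity_fn(choice, cement, medium,
                                           controls$mobility_floor),
              visc_M = .build_viscosity_fn(choice, marrow, medium,
                                           controls$mobility_floor),
              visc_bounds_C = c(cement$mu_inf, cement$mu0),
              visc_bounds_M = c(marrow$mu_inf, marrow$mu0),
              face_mu_C = .build_face_mu_fn(choice, cement, medium,
                                            controls$mobility_floor),
              face_mu_M = .build_face_mu_fn(choice, marrow, medium,
                                            controls$mobility_floor),
              Xfac_C = .build_Xfac_fn(choice, cement, medium,
                                      controls$mobility_floor),
              Xfac_M = .build_Xfac_fn(choice, marrow, medium,
                                      controls$mobility_floor))
  class(sys) <- "injection_system"
  sys
}

#' @export
print.injection_system <- function(x, ...) {
  cat(sprintf("<injection_system> %d cells, %d vertices, %d dofs, upscaling: %s\n",
              x$nc, x$nv, x$ndof, x$choice$model))
  invisible(x)
}

.state_to_x <- function(sys, state) {
  x <- numeric(sys$ndof)
  v <- seq_len(sys$nv)
  for (comp in 1:3) x[.idx_u(v, comp)] <- state$u[, comp]
  x[.idx_p(v)] <- state$p
  x[.idx_s(v)] <- state$sM
  x
}

.x_to_state <- function(sys, x, t) {
  v <- seq_len(sys$nv)
  structure(list(u = cbind(x[.idx_u(v, 1)], x[.idx_u(v, 2)], x[.idx_u(v, 3)]),
                 p = x[.idx_p(v)], sM = x[.idx_s(v)], t = t),
            class = "mixture_state")
}

.brooks_corey_fast <- function(lambda_bc, sM) {
  s <- pmin(pmax(sM, 0), 1)
  list(kr_C = (1 - s)^2 * (1 - s^((2 + lambda_bc) / lambda_bc)),
       kr_M = s^((2 + 3 * lambda_bc) / lambda_bc))
}

# Local effective viscosity at integration points. The self-consistency
# condition mu = mu_upscaled(w) with w = X / mu reduces, for every upscaling
# model, to a one-parameter family in X (= seepage velocity times viscosity,
# rescaled by the model's constants): its unique root (the map
# log V(X/exp(phi)) - phi is strictly decreasing since
# |d log mu / d log w| <= 1 - n_rh < 1 for Carreau) is tabulated once per
# phase on a wide log grid by vectorized bisection and interpolated with a
# monotone Hermite spline. Faces then cost one spline evaluation.
.build_face_mu_fn <- function(choice, params, medium, kr_floor = 1e-6) {
  mu0 <- params$mu0; mu_inf <- params$mu_inf
  if (mu0 == mu_inf || params$n_rh == 1)
    return(function(X) rep(mu0, length(X)))
  # V(w): effective viscosity as a function of the velocity-like argument;
  # for the semi-empirical models X already carries C, the shape factor and
  # the sqrt(n_beta/(8 kr K)) factor, so V is the bare Carreau law
  V <- if (choice$model %in% c("cannella", "hirasaki_pope")) {
    function(w) carreau_viscosity(params, w)
  } else {
    avg <- .build_viscosity_fn(upscaling_choice("average_viscosity"),
                               params, medium, kr_floor)
    function(w) avg(w, NULL, NULL)
  }
  # X = gamma_dot * mu for the semi-empirical models (units Pa), or
  # w * mu for the average model: cover both with a generous range
  lX <- seq(log(mu_inf) - 32, log(mu0) + 36, length.out = 900)
  lo <- rep(log(mu_inf) - 1e-3, length(lX))
  hi <- rep(log(mu0) + 1e-3, length(lX))
  X <- exp(lX)
  for (k in 1:50) {
    mid <- 0.5 * (lo + hi)
    G <- log(V(X / exp(mid))) - mid
    below <- G < 0
    hi[below] <- mid[below]
    lo[!below] <- mid[!below]
  }
  lmu <- 0.5 * (lo + hi)
  sf <- stats::splinefun(lX, lmu, method = "monoH.FC")
  rng <- range(lX)
  function(X) {
    lx <- pmin(pmax(log(pmax(X, 1e-300)), rng[1]), rng[2])
    pmin(pmax(exp(sf(lx)), mu_inf), mu0)
  }
}

# scale factor turning the velocity-viscosity product w * mu into the lookup
# argument X of .build_face_mu_fn: for the semi-empirical models X is the
# effective shear rate times viscosity, i.e. w * mu times the Eq.-15 factor
# (with the relative permeability floored inside the square root); for the
# average-viscosity model X is w * mu itself.
.build_Xfac_fn <- function(choice, params, medium, kr_floor = 1e-6) {
  if (!choice$model %in% c("cannella", "hirasaki_pope"))
    return(function(nb, kr) 1)
  if (params$n_rh == 1 || params$mu0 == params$mu_inf)
    return(function(nb, kr) 1)
  n <- params$n_rh
  shape <- ((3 * n + 1) / (4 * n))^(n / (n - 1))
  Cc <- choice$C_const
  K <- medium$K_S
  function(nb, kr)
    Cc * shape * 4 * sqrt(pmax(nb, 0) / (8 * pmax(kr, kr_floor) * K))
}

# cell-local fluid residual contributions (cement Rc and marrow Rm, nc x 8).
# P, S: nodal values gathered per cell; divu: cell dilatations. Effective
# viscosities are evaluated locally at each SCVF from the upwind saturation
# and the pressure-gradient magnitude at the integration point.
.fluid_local <- function(sys, P, S, P0, S0, divu, divu0, dt,
                         with_scale = FALSE) {
  med <- sys$medium
  nS_new <- med$nS_0S / (1 + divu)
  nS_old <- med$nS_0S / (1 + divu0)
  nF_new <- 1 - nS_new
  nF_old <- 1 - nS_old
  divdot <- (divu - divu0) / dt
  nC <- nF_new * (1 - S); nC0 <- nF_old * (1 - S0)
  nM <- nF_new * S;       nM0 <- nF_old * S0
  V <- sys$scv_vol
  Rc <- V * ((nC - nC0) / dt + nC * divdot)
  Rm <- V * ((nM - nM0) / dt + nM * divdot)
  K <- med$K_S
  lam <- med$lambda_bc
  nc <- sys$nc
  Qd <- matrix(0, nc, 12)
  Gm <- matrix(0, nc, 12)
  Sup <- matrix(0, nc, 12)
  for (e in 1:12) {
    gNe <- sys$gN[[e]]
    gp1 <- rowSums(gNe[[1]] * P)
    gp2 <- rowSums(gNe[[2]] * P)
    gp3 <- rowSums(gNe[[3]] * P)
    nve <- sys$nvec[[e]]
    Qd[, e] <- -(gp1 * nve[[1]] + gp2 * nve[[2]] + gp3 * nve[[3]])
    Gm[, e] <- sqrt(gp1^2 + gp2^2 + gp3^2)
    a <- .hex_edges[e, 1]; b <- .hex_edges[e, 2]
    Sup[, e] <- ifelse(Qd[, e] > 0, S[, a], S[, b])
  }
  kr <- .brooks_corey_fast(lam, as.vector(Sup))
  gmag <- as.vector(Gm)
  nbC <- rep(nF_new, 12) * (1 - as.vector(pmin(pmax(Sup, 0), 1)))
  nbM <- rep(nF_new, 12) * as.vector(pmin(pmax(Sup, 0), 1))
  muC <- sys$face_mu_C(kr$kr_C * K * gmag / pmax(nbC, 1e-9) *
                       sys$Xfac_C(nbC, kr$kr_C))
  muM <- sys$face_mu_M(kr$kr_M * K * gmag / pmax(nbM, 1e-9) *
                       sys$Xfac_M(nbM, kr$kr_M))
  FC <- matrix(kr$kr_C / muC, nc, 12) * K * Qd
  FM <- matrix(kr$kr_M / muM, nc, 12) * K * Qd
  Ac <- Am <- NULL
  if (with_scale) { Ac <- abs(Rc); Am <- abs(Rm) }
  for (e in 1:12) {
    a <- .hex_edges[e, 1]; b <- .hex_edges[e, 2]
    Rc[, a] <- Rc[, a] + FC[, e]; Rc[, b] <- Rc[, b] - FC[, e]
    Rm[, a] <- Rm[, a] + FM[, e]; Rm[, b] <- Rm[, b] - FM[, e]
    if (with_scale) {
      Ac[, a] <- Ac[, a] + abs(FC[, e]); Ac[, b] <- Ac[, b] + abs(FC[, e])
      Am[, a] <- Am[, a] + abs(FM[, e]); Am[, b] <- Am[, b] + abs(FM[, e])
    }
  }
  list(Rc = Rc, Rm = Rm, Ac = Ac, Am = Am)
}

.gather <- function(sys, v) matrix(v[sys$cells], sys$nc, 8)

.cell_div_u <- function(sys, u) {
  rowSums(sys$g0[[1]] * .gather(sys, u[, 1])) +
  rowSums(sys$g0[[2]] * .gather(sys, u[, 2])) +
  rowSums(sys$g0[[3]] * .gather(sys, u[, 3]))
}

# nodal effective viscosities from the seepage-velocity magnitudes of the
# previous fixed-point sweep (diagnostics only). mu_prev: list(C, M).
.nodal_viscosity <- function(sys, state, mu_prev) {
  med <- sys$medium
  P <- .gather(sys, state$p)
  gp1 <- rowSums(sys$g0[[1]] * P)
  gp2 <- rowSums(sys$g0[[2]] * P)
  gp3 <- rowSums(sys$g0[[3]] * P)
  gmag <- sqrt(gp1^2 + gp2^2 + gp3^2)
  # volume-weighted projection of the cell-centre |grad p| to vertices, then
  # per-vertex Darcy seepage with nodal saturation/permeability (so a vertex
  # on the displacement front sees its own mobility, not a cell average)
  Vs <- as.vector(sys$scv_vol)
  idx <- as.vector(sys$cells)
  acc <- rowsum(Vs * rep(gmag, 8), idx)
  gv <- numeric(sys$nv)
  gv[as.integer(rownames(acc))] <- acc[, 1]
  gv <- gv / pmax(sys$vert_vol, 1e-300)
  s <- pmin(pmax(state$sM, 0), 1)
  krv <- .brooks_corey_fast(med$lambda_bc, s)
  nF <- med$n_F
  nC_v <- nF * (1 - s); nM_v <- nF * s
  wC <- krv$kr_C * med$K_S / mu_prev$C * gv / pmax(nC_v, 1e-6)
  wM <- krv$kr_M * med$K_S / mu_prev$M * gv / pmax(nM_v, 1e-6)
  list(C = sys$visc_C(wC, nC_v, krv$kr_C),
       M = sys$visc_M(wM, nM_v, krv$kr_M),
       wC = wC, wM = wM)
}

# self-consistent nodal effective viscosity of a converged state, used for
# reporting and field output (the solver itself evaluates viscosities
# locally at integration points): iterate the cheap nodal fixed point
# mu -> viscosity(seepage(mu)) to stagnation, with log-space damping.
.nodal_viscosity_diag <- function(sys, state, tol = 1e-10, max_iter = 60) {
  mu <- list(C = rep(sys$cement$mu0, sys$nv),
             M = rep(sys$marrow$mu0, sys$nv))
  for (k in seq_len(max_iter)) {
    mu_new <- .nodal_viscosity(sys, state, mu)
    dC <- max(abs(log(mu_new$C / mu$C)))
    dM <- max(abs(log(mu_new$M / mu$M)))
    mu <- list(C = exp(0.5 * (log(mu_new$C) + log(mu$C))),
               M = exp(0.5 * (log(mu_new$M) + log(mu$M))),
               wC = mu_new$wC, wM = mu_new$wM)
    if (max(dC, dM) < tol) break
  }
  mu
}

# full residual vector at x; with_scale additionally returns the per-row sum
# of absolute term magnitudes (denominator of a backward-error criterion)
.residual_vec <- function(sys, x, state_old, dt, with_scale = FALSE) {
  st <- .x_to_state(sys, x, state_old$t + dt)
  P <- .gather(sys, st$p); S <- .gather(sys, st$sM)
  P0 <- .gather(sys, state_old$p); S0 <- .gather(sys, state_old$sM)
  divu <- .cell_div_u(sys, st$u); divu0 <- .cell_div_u(sys, state_old$u)
  loc <- .fluid_local(sys, P, S, P0, S0, divu, divu0, dt, with_scale)
  r <- numeric(sys$ndof)
  idxp <- .idx_p(as.vector(sys$cells)); idxs <- .idx_s(as.vector(sys$cells))
  accC <- rowsum(as.vector(loc$Rc), idxp)
  accM <- rowsum(as.vector(loc$Rm), idxs)
  r[as.integer(rownames(accC))] <- accC[, 1]
  r[as.integer(rownames(accM))] <- accM[, 1]
  r <- r - sys$b_in
  r <- r + as.numeric(sys$Amom %*% x)
  r[sys$dir_dofs] <- x[sys$dir_dofs] - sys$dir_vals
  if (!with_scale) return(r)
  sc <- numeric(sys$ndof)
  accC <- rowsum(as.vector(loc$Ac), idxp)
  accM <- rowsum(as.vector(loc$Am), idxs)
  sc[as.integer(rownames(accC))] <- accC[, 1]
  sc[as.integer(rownames(accM))] <- accM[, 1]
  sc <- sc + abs(sys$b_in)
  sc <- sc + as.numeric(sys$absAmom %*% abs(x))
  # Dirichlet rows are satisfied exactly from the first update onwards;
  # exclude them from the convergence metric so they cannot mask (or fake)
  # imbalance in the physical rows
  sc[sys$dir_dofs] <- 0
  list(r = r, scale = sc)
}

#' Assemble the monolithic residual
#'
#' Full nonlinear residual of the coupled system at `state_new` given the
#' converged previous state: Galerkin momentum rows, Box-FV cement and
#' marrow volume-balance rows with mass-lumped implicit-Euler storage and
#' fully-upwind mobilities, Dirichlet rows replaced by constraint residuals.
#' Effective viscosities are resolved locally at each face from `state_new`
#' itself, so a converged state has residual zero in the fully coupled sense.
#'
#' @param sys An `injection_system`.
#' @param state_new,state_old `mixture_state`s sharing the system mesh.
#' @param dt Time-step size \[s\] (defaults to the time difference).
#' @return Residual vector of length `5 * n_vertices`.
#' @export
assemble_residual <- function(sys, state_new, state_old,
                              dt = state_new$t - state_old$t) {
  stopifnot(inherits(sys, "injection_system"), dt > 0)
  if (any(!is.finite(state_new$p)) || any(!is.finite(state_new$sM)) ||
      any(!is.finite(state_new$u)))
    stop("assemble_residual: non-finite entries in state", call. = FALSE)
  .residual_vec(sys, .state_to_x(sys, state_new), state_old, dt)
}

# fluid Jacobian by cell-local finite differences (16 perturbations), plus
# the analytic solid-dilatation coupling block and the constant momentum
# block; Dirichlet rows replaced by identity.
.jacobian <- function(sys, x, state_old, dt) {
  st <- .x_to_state(sys, x, state_old$t + dt)
  P <- .gather(sys, st$p); S <- .gather(sys, st$sM)
  P0 <- .gather(sys, state_old$p); S0 <- .gather(sys, state_old$sM)
  divu <- .cell_div_u(sys, st$u); divu0 <- .cell_div_u(sys, state_old$u)
  base <- .fluid_local(sys, P, S, P0, S0, divu, divu0, dt)
  nc <- sys$nc
  Jx <- array(0, c(nc, 16, 16))
  hp <- 1e-7 * max(1, max(abs(st$p)))
  hs <- 1e-7
  for (a in 1:8) {
    P2 <- P; P2[, a] <- P2[, a] + hp
    loc <- .fluid_local(sys, P2, S, P0, S0, divu, divu0, dt)
    Jx[, , a] <- cbind((loc$Rc - base$Rc) / hp, (loc$Rm - base$Rm) / hp)
    S2 <- S; S2[, a] <- S2[, a] + hs
    loc <- .fluid_local(sys, P, S2, P0, S0, divu, divu0, dt)
    Jx[, , 8 + a] <- cbind((loc$Rc - base$Rc) / hs, (loc$Rm - base$Rm) / hs)
  }
  # analytic u-coupling of the storage + dilatation terms:
  # dR/d u[b,k] = V/dt * (nS0 * s_phase + n_phase) * gradN0[b,k]
  med <- sys$medium
  nF_new <- 1 - med$nS_0S / (1 + divu)
  Bx <- array(0, c(nc, 16, 24))
  for (a in 1:8) {
    cC <- sys$scv_vol[, a] / dt * (med$nS_0S * (1 - S[, a]) +
                                   nF_new * (1 - S[, a]))
    cM <- sys$scv_vol[, a] / dt * (med$nS_0S * S[, a] + nF_new * S[, a])
    for (b in 1:8) for (k in 1:3) {
      g <- sys$g0[[k]][, b]
      Bx[, a, (k - 1) * 8 + b] <- cC * g
      Bx[, 8 + a, (k - 1) * 8 + b] <- cM * g
    }
  }
  nv <- sys$nv
  Fm <- Matrix::sparseMatrix(i = sys$iF, j = sys$jF, x = as.vector(Jx),
                             dims = c(2L * nv, 2L * nv))
  Bm <- Matrix::sparseMatrix(i = sys$iB, j = sys$jB, x = as.vector(Bx),
                             dims = c(2L * nv, 3L * nv))
  DfF <- Matrix::Diagonal(x = sys$freeF)
  Fm <- DfF %*% Fm + Matrix::Diagonal(x = 1 - sys$freeF)
  Bm <- DfF %*% Bm
  # equilibrated LU of the fluid block (dynamic pressure column scale)
  p_sc <- max(abs(st$p), 1e3)
  colsc <- c(rep(p_sc, nv), rep(1, nv))
  DcF <- Matrix::Diagonal(x = colsc)
  Fs <- Fm %*% DcF
  rsF <- pmax(Matrix::rowSums(abs(Fs)), 1e-300)
  DrF <- Matrix::Diagonal(x = 1 / rsF)
  FsS <- DrF %*% Fs
  luF <- Matrix::lu(FsS)
  dU <- abs(Matrix::diag(luF@U))
  if (min(dU) < 1e-14 * max(dU)) {
    # near-singular pivot (e.g. a phase locally immobile on all its faces):
    # refactor with a tiny diagonal shift; the Newton residual check keeps
    # the outer iteration honest
    luF <- Matrix::lu(FsS + 1e-12 * Matrix::Diagonal(2L * nv))
  }
  list(Fm = Fm, Bm = Bm, luF = luF, DrF = DrF, colscF = colsc)
}

# solve the monolithic linearized system by exact block factorizations with
# two block Gauss-Seidel sweeps (the fluid->solid->fluid coupling product is
# O(1e-15) at these parameters, far below Newton tolerance)
.block_solve <- function(sys, jac, r) {
  nv <- sys$nv
  rf <- r[sys$fdofs5]
  ru <- r[sys$udofs5]
  solveF <- function(b) {
    y <- Matrix::solve(jac$luF, as.numeric(jac$DrF %*% b))
    jac$colscF * as.numeric(y)
  }
  solveU <- function(b) as.numeric(Matrix::solve(sys$luU,
                                                 as.numeric(sys$DrU %*% b)))
  dxf <- solveF(-rf)
  for (sweep in 1:2) {
    dxu <- solveU(-ru - as.numeric(sys$Cup %*% dxf[seq_len(nv)]))
    res_f <- rf + as.numeric(jac$Fm %*% dxf) + as.numeric(jac$Bm %*% dxu)
    dxf <- dxf - solveF(res_f)
  }
  dxu <- solveU(-ru - as.numeric(sys$Cup %*% dxf[seq_len(nv)]))
  dx <- numeric(sys$ndof)
  dx[sys$fdofs5] <- dxf
  dx[sys$udofs5] <- dxu
  dx
}

.block_norms <- function(sys, r) {
  v <- seq_len(sys$nv)
  c(u = sqrt(sum(r[.idx_u(v, 1)]^2 + r[.idx_u(v, 2)]^2 + r[.idx_u(v, 3)]^2)),
    p = sqrt(sum(r[.idx_p(v)]^2)),
    s = sqrt(sum(r[.idx_s(v)]^2)))
}

#' One implicit-Euler step solved by Newton's method
#'
#' Monolithic Newton iteration with the effective viscosity resolved locally
#' at each sub-control-volume face (so the cell-local finite-difference fluid
#' Jacobian carries the full shear-thinning feedback), block-factorized
#' linear solves, a trust cap on the pressure update, a backtracking line
#' search, and saturation clamping after each update. Convergence is a
#' backward-error criterion per equation block: the residual norm must fall
#' below `newton_tol` times the norm of the summed absolute magnitudes of
#' the terms composing the rows (Dirichlet rows excluded).
#'
#' @param sys An `injection_system`.
#' @param state_old Converged state at the previous time level.
#' @param dt Time-step size \[s\].
#' @param state0 Optional initial guess (defaults to `state_old`).
#' @return List with `state` (converged `mixture_state`), `converged`,
#'   `iterations`, `res_history` (per-iteration block-relative norms),
#'   `clamped` (number of saturation values clamped), `mu` (nodal effective
#'   viscosities), `w` (nodal seepage magnitudes).
#' @export
newton_step <- function(sys, state_old, dt, state0 = NULL) {
  ctrl <- sys$controls
  x <- .state_to_x(sys, if (is.null(state0)) state_old else state0)
  x[sys$dir_dofs] <- sys$dir_vals
  res_hist <- list()
  J <- NULL
  prev_norm <- Inf
  clamped_total <- 0L
  converged <- FALSE
  sidx <- .idx_s(seq_len(sys$nv))
  # backward-error convergence: per block, the residual norm is compared to
  # the norm of the absolute magnitudes of the terms composing it (plus the
  # inflow scale, so an equation whose terms all vanish is judged converged)
  eval_point <- function(x) {
    out <- tryCatch(.residual_vec(sys, x, state_old, dt, with_scale = TRUE),
                    error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out$r))) return(NULL)
    rr <- out$r
    rr[sys$dir_dofs] <- 0
    nb <- .block_norms(sys, rr)
    ns <- .block_norms(sys, out$scale)
    out$rel <- ifelse(nb == 0, 0, nb / pmax(ns, .Machine$double.xmin))
    out
  }
  for (it in seq_len(ctrl$newton_max_iter)) {
    ev <- eval_point(x)
    if (is.null(ev)) break
    rel <- ev$rel
    res_hist[[it]] <- rel
    if (all(rel <= ctrl$newton_tol)) { converged <- TRUE; break }
    if (it == ctrl$newton_max_iter) break
    if (it >= 16 && max(rel) > 0.3) break   # not going to make it: fail fast
    if (is.null(J) || max(rel) > 0.2 * prev_norm || it %% 8 == 0)
      J <- tryCatch(.jacobian(sys, x, state_old, dt),
                    error = function(e) NULL)
    prev_norm <- max(rel)
    dx <- if (is.null(J)) NULL else
      tryCatch(.block_solve(sys, J, ev$r), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) { J <- NULL; break }
    # trust cap on the pressure update: the effective viscosity can drop by
    # orders of magnitude across one step, so let the pressure scale grow
    # progressively instead of overshooting with the local linearization
    pidx <- .idx_p(seq_len(sys$nv))
    dxp_max <- max(abs(dx[pidx]))
    cap <- max(1e6, 30 * max(abs(x[pidx])))
    if (dxp_max > cap) dx <- dx * (cap / dxp_max)
    # backtracking line search on the backward-error metric
    alpha <- 1
    best <- NULL
    best_rel <- Inf
    for (k in 1:12) {
      xt <- x + alpha * dx
      xt[sidx] <- pmin(pmax(xt[sidx], 0), 1)
      et <- eval_point(xt)
      if (!is.null(et)) {
        m <- max(et$rel)
        if (m < max(rel)) { best <- xt; break }
        if (m < best_rel) { best <- xt; best_rel <- m }
      }
      alpha <- alpha / 2
    }
    if (is.null(best)) break
    sv <- x[sidx] + alpha * dx[sidx]
    clamped_total <- clamped_total + sum(sv < -1e-8 | sv > 1 + 1e-8)
    x <- best
  }
  st <- .x_to_state(sys, x, state_old$t + dt)
  mu <- .nodal_viscosity_diag(sys, st)
  attr(st, "mu") <- mu[c("C", "M")]
  list(state = st, converged = converged, iterations = length(res_hist),
       res_history = res_hist, clamped = clamped_total,
       mu = mu[c("C", "M")], w = list(C = mu$wC, M = mu$wM))
}

# domain cement volume by SCV integration, consistent with the storage terms
.domain_cement_volume <- function(sys, state) {
  divu <- .cell_div_u(sys, state$u)
  nF <- 1 - sys$medium$nS_0S / (1 + divu)
  S <- .gather(sys, pmin(pmax(state$sM, 0), 1))
  sum(sys$scv_vol * nF * (1 - S))
}

.inlet_pressure <- function(sys, state) {
  v <- sys$inflow_vertices
  if (length(v) == 0) return(NA_real_)
  w <- sys$b_in[.idx_p(v)]      # proportional to sub-areas
  sum(state$p[v] * w) / sum(w)
}

# volume-weighted median of a nodal field over the interior region where the
# phase is the majority pore occupant
.bulk_median <- function(sys, field, weight_mask) {
  sel <- which(weight_mask & sys$interior_mask)
  if (length(sel) == 0) sel <- which(weight_mask)
  if (length(sel) == 0) return(NA_real_)
  w <- sys$vert_vol[sel]
  o <- order(field[sel])
  cw <- cumsum(w[o]) / sum(w)
  field[sel][o][which(cw >= 0.5)[1]]
}

#' March the coupled system through time
#'
#' Implicit-Euler time stepping with [newton_step()]; a failed step is
#' retried with halved dt (up to `max_halvings`), and the base dt is
#' restored afterwards. Records the injection time series at every accepted
#' step and optionally writes VTK snapshots.
#'
#' @param sys An `injection_system`.
#' @param t_end End time \[s\].
#' @param state0 Initial `mixture_state` (default: undeformed, p = 0,
#'   marrow-saturated).
#' @param snapshot_times Times at which to write VTK field snapshots.
#' @param out_dir Directory for snapshots (created if needed).
#' @param verbose Print per-step progress.
#' @return List of class `march_result`: `timeseries` (tibble with time,
#'   inlet pressure, injected and domain cement volumes, max displacement,
#'   bulk effective viscosities, Newton iterations), `final` state,
#'   `snapshots` (paths), `newton_failures`.
#' @export
time_march <- function(sys, t_end, state0 = NULL, snapshot_times = numeric(),
                       out_dir = NULL, verbose = FALSE) {
  ctrl <- sys$controls
  state <- if (is.null(state0)) mixture_state(sys$topo) else state0
  base_dt <- ctrl$dt
  rows <- list()
  snaps <- character(0)
  snap_left <- sort(snapshot_times[snapshot_times > state$t &
                                   snapshot_times <= t_end])
  failures <- 0L
  t <- state$t
  k <- 0L
  # ramp the step in from a cold start: the first increments drive the
  # displacement front through the inlet control volumes, the stiffest part
  # of the whole run
  dt_cur <- if (max(abs(state$p)) == 0) base_dt / 8 else base_dt
  streak <- 0L
  while (t < t_end - 1e-12 * max(1, t_end)) {
    dt <- min(dt_cur, t_end - t)
    if (length(snap_left) > 0) dt <- min(dt, snap_left[1] - t)
    halved <- 0
    repeat {
      # warm start by linear extrapolation in time from the last two states
      guess <- NULL
      if (!is.null(attr(state, "prev")) && halved == 0) {
        prev <- attr(state, "prev")
        dtp <- state$t - prev$t
        if (dtp > 0) {
          f <- dt / dtp
          guess <- state
          guess$p <- state$p + f * (state$p - prev$p)
          guess$sM <- pmin(pmax(state$sM + f * (state$sM - prev$sM), 0), 1)
          guess$u <- state$u + f * (state$u - prev$u)
        }
      }
      stp <- newton_step(sys, state, dt, state0 = guess)
      if (stp$converged) break
      halved <- halved + 1
      failures <- failures + 1L
      if (halved > ctrl$max_halvings)
        stop(sprintf("time_march: step at t = %g failed after %d dt halvings",
                     t, ctrl$max_halvings), call. = FALSE)
      dt <- dt / 2
      dt_cur <- dt
      streak <- 0L
    }
    streak <- streak + 1L
    if (streak >= 2L && dt_cur < base_dt) {
      dt_cur <- min(2 * dt_cur, base_dt)
      streak <- 0L
    }
    prev_state <- state
    attr(prev_state, "prev") <- NULL
    state <- stp$state
    attr(state, "prev") <- prev_state
    t <- state$t
    k <- k + 1L
    mu <- stp$mu
    sC <- 1 - pmin(pmax(state$sM, 0), 1)
    rows[[k]] <- c(
      time = t,
      inlet_pressure = .inlet_pressure(sys, state),
      injected_volume = sys$Q_total * t,
      cement_volume = .domain_cement_volume(sys, state),
      max_displacement = max(abs(state$u)),
      bulk_visc_cement = .bulk_median(sys, mu$C, sC > 0.5),
      bulk_visc_marrow = .bulk_median(sys, mu$M, sC <= 0.5),
      newton_iter = stp$iterations,
      clamped = stp$clamped)
    if (verbose)
      message(sprintf("t = %6.3f s  p_in = %10.4g Pa  iters = %d",
                      t, rows[[k]][["inlet_pressure"]], stp$iterations))
    if (length(snap_left) > 0 && abs(t - snap_left[1]) < 1e-9 * max(1, t)) {
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        path <- file.path(out_dir,
                          sprintf("snapshot_%04d.vtk", length(snaps) + 1))
        write_vtk(sys$mesh,
                  fields = list(u_S = state$u, p = state$p, sM = state$sM,
                                sC = 1 - state$sM, mu_C = mu$C, mu_M = mu$M),
                  path = path)
        snaps <- c(snaps, path)
      }
      snap_left <- snap_left[-1]
    }
  }
  ts <- tibble::as_tibble(do.call(rbind, rows))
  structure(list(timeseries = ts, final = state, snapshots = snaps,
                 newton_failures = failures, system = sys),
            class = "march_result")
}
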