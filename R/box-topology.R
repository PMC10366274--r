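# Vertex-centered finite-volume (Box) dual topology on trilinear hexahedra.
#
# Each cell is split at edge midpoints, face centroids and the cell centroid
# into 8 sub-control volumes (SCV), one per cell vertex; in reference
# coordinates the SCV of vertex a is the octant between a and the centre.
# The 12 internal splitting quads are the sub-control-volume faces (SCVF),
# one per cell edge, oriented from the first to the second edge vertex.

#' Build the Box-scheme dual topology of a hexahedral mesh
#'
#' Precomputes, for every cell: the 8 sub-control-volume volumes (exact
#' octant integrals of the trilinear Jacobian, so they sum to the exact cell
#' volume), the 12 internal sub-control-volume faces with area vectors
#' oriented along the corresponding cell edge, shape-function values and
#' physical gradients at the face integration points, shape gradients at the
#' cell centre (for solid-dilatation coupling), and per-vertex sub-areas of
#' every tagged boundary facet.
#'
#' @param mesh A `hex_mesh`.
#' @return An object of class `box_topology`.
#' @export
build_box_topology <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  Xc <- .cell_coord_list(mesh)
  nc <- nrow(mesh$cells)
  nv <- nrow(mesh$vertices)

  # positivity check at the corners
  for (a in c(1, 7)) {
    d <- .hex_geom_at(Xc, .hex_ref_nodes[a, ], grad = FALSE)$detJ
    if (any(d <= 0)) stop("degenerate cell: non-positive Jacobian",
                          call. = FALSE)
  }

  # SCV volumes: 2x2x2 Gauss on each reference octant
  scv_vol <- matrix(0, nc, 8)
  for (a in 1:8) {
    ctr <- .hex_ref_nodes[a, ] / 2
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      # octant spans [0, ref_a] per axis: centre ref_a/2, half-width 1/2
      xi <- ctr + c(sx, sy, sz) * (.gauss2 / 2)
      scv_vol[, a] <- scv_vol[, a] +
        .hex_geom_at(Xc, xi, grad = FALSE)$detJ / 8
    }
  }

  # SCVFs
  map_pt <- function(xi) {
    N <- .hex_shape(xi)$N
    lapply(1:3, function(i) drop(Xc[[i]] %*% N))
  }
  scvf_n <- array(0, c(nc, 12, 3))
  scvf_gradN <- array(0, c(nc, 12, 8, 3))
  for (e in 1:12) {
    q <- lapply(1:4, function(k) map_pt(.box_ref$corners[e, k, ]))
    d1 <- lapply(1:3, function(i) q[[3]][[i]] - q[[1]][[i]])
    d2 <- lapply(1:3, function(i) q[[4]][[i]] - q[[2]][[i]])
    nvec <- list(0.5 * (d1[[2]] * d2[[3]] - d1[[3]] * d2[[2]]),
                 0.5 * (d1[[3]] * d2[[1]] - d1[[1]] * d2[[3]]),
                 0.5 * (d1[[1]] * d2[[2]] - d1[[2]] * d2[[1]]))
    a <- .hex_edges[e, 1]; b <- .hex_edges[e, 2]
    tvec <- lapply(1:3, function(i) Xc[[i]][, b] - Xc[[i]][, a])
    s <- sign(nvec[[1]] * tvec[[1]] + nvec[[2]] * tvec[[2]] +
              nvec[[3]] * tvec[[3]])
    s[s == 0] <- 1
    for (i in 1:3) scvf_n[, e, i] <- nvec[[i]] * s
    scvf_gradN[, e, , ] <- .hex_geom_at(Xc, .box_ref$ip[e, ])$gradN
  }

  gradN0 <- .hex_geom_at(Xc, c(0, 0, 0))$gradN
  cell_vol <- rowSums(scv_vol)

  # boundary facet sub-areas (one quarter-quad per facet vertex)
  bnd <- mesh$boundary
  V <- mesh$vertices
  p <- lapply(1:4, function(k) V[bnd[[paste0("v", k)]], , drop = FALSE])
  cen <- (p[[1]] + p[[2]] + p[[3]] + p[[4]]) / 4
  m <- list(`12` = (p[[1]] + p[[2]]) / 2, `23` = (p[[2]] + p[[3]]) / 2,
            `34` = (p[[3]] + p[[4]]) / 2, `41` = (p[[4]] + p[[1]]) / 2)
  quad_area <- function(a, b, c2, d) {
    d1 <- c2 - a; d2 <- d - b
    n <- 0.5 * cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                     d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                     d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
    sqrt(rowSums(n^2))
  }
  bnd_subarea <- cbind(quad_area(p[[1]], m[["12"]], cen, m[["41"]]),
                       quad_area(p[[2]], m[["23"]], cen, m[["12"]]),
                       quad_area(p[[3]], m[["34"]], cen, m[["23"]]),
                       quad_area(p[[4]], m[["41"]], cen, m[["34"]]))

  structure(list(mesh = mesh, nc = nc, nv = nv,
                 scv_vol = scv_vol, scvf_n = scvf_n,
                 scvf_N = .box_ref$Nip, scvf_gradN = scvf_gradN,
                 edge_pair = .hex_edges, gradN0 = gradN0,
                 cell_vol = cell_vol, bnd_subarea = bnd_subarea),
            class = "box_topology")
}

#' @export
print.box_topology <- function(x, ...) {
  cat(sprintf("<box_topology> %d cells, %d vertices, total volume %.6g m^3\n",
              x$nc, x$nv, sum(x$cell_vol)))
  invisible(x)
}

#' Per-vertex control volumes
#'
#' Volume of the box control volume of every vertex (sum of its sub-control
#' volumes over adjacent cells); these are the mass-lumping weights.
#'
#' @param topo A `box_topology`.
#' @return Numeric vector of length `n_vertices` \[m^3\].
#' @export
vertex_volumes <- function(topo) {
  v <- numeric(topo$nv)
  s <- rowsum(as.vector(topo$scv_vol), as.vector(topo$mesh$cells))
  v[as.integer(rownames(s))] <- s[, 1]
  v
}
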