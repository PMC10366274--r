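# Reference trilinear hexahedron (VTK node ordering) shared by the mesh and
# Box-topology code: [-1,1]^3 with nodes
#   1(-,-,-) 2(+,-,-) 3(+,+,-) 4(-,+,-) 5(-,-,+) 6(+,-,+) 7(+,+,+) 8(-,+,+)

.hex_ref_nodes <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                           -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                         ncol = 3, byrow = TRUE)

# faces ordered outward (counter-clockwise seen from outside)
.hex_faces <- list(zmin = c(1, 4, 3, 2), zmax = c(5, 6, 7, 8),
                   ymin = c(1, 2, 6, 5), xmax = c(2, 3, 7, 6),
                   ymax = c(3, 4, 8, 7), xmin = c(4, 1, 5, 8))

.hex_edges <- matrix(c(1, 2, 2, 3, 3, 4, 4, 1,
                       5, 6, 6, 7, 7, 8, 8, 5,
                       1, 5, 2, 6, 3, 7, 4, 8), ncol = 2, byrow = TRUE)

# the two faces adjacent to each edge (indices into .hex_faces)
.hex_edge_faces <- matrix(c(1, 3,  1, 4,  1, 5,  1, 6,
                            2, 3,  2, 4,  2, 5,  2, 6,
                            3, 6,  3, 4,  4, 5,  5, 6), ncol = 2, byrow = TRUE)

.gauss2 <- 1 / sqrt(3)

# trilinear shape functions and reference gradients at one reference point
.hex_shape <- function(xi) {
  rn <- .hex_ref_nodes
  N <- (1 + rn[, 1] * xi[1]) * (1 + rn[, 2] * xi[2]) *
       (1 + rn[, 3] * xi[3]) / 8
  dN <- cbind(rn[, 1] * (1 + rn[, 2] * xi[2]) * (1 + rn[, 3] * xi[3]),
              rn[, 2] * (1 + rn[, 1] * xi[1]) * (1 + rn[, 3] * xi[3]),
              rn[, 3] * (1 + rn[, 1] * xi[1]) * (1 + rn[, 2] * xi[2])) / 8
  list(N = N, dN = dN)
}

# Vectorized trilinear geometry at one reference point for all cells.
# Xc: list of three nc x 8 matrices (x, y, z of the 8 nodes per cell).
# Returns detJ (nc) and, if grad = TRUE, physical shape gradients (nc x 8 x 3).
.hex_geom_at <- function(Xc, xi, grad = TRUE) {
  sh <- .hex_shape(xi)
  dN <- sh$dN
  J <- vector("list", 3)
  for (i in 1:3) J[[i]] <- lapply(1:3, function(j) drop(Xc[[i]] %*% dN[, j]))
  a11 <- J[[1]][[1]]; a12 <- J[[1]][[2]]; a13 <- J[[1]][[3]]
  a21 <- J[[2]][[1]]; a22 <- J[[2]][[2]]; a23 <- J[[2]][[3]]
  a31 <- J[[3]][[1]]; a32 <- J[[3]][[2]]; a33 <- J[[3]][[3]]
  c11 <- a22 * a33 - a23 * a32
  c12 <- a23 * a31 - a21 * a33
  c13 <- a21 * a32 - a22 * a31
  detJ <- a11 * c11 + a12 * c12 + a13 * c13
  out <- list(detJ = detJ, N = sh$N)
  if (grad) {
    # invJ[j,i] = cof(J)[i,j] / detJ ; gradN_phys[a,i] = sum_j dN[a,j] invJ[j,i]
    inv <- list(
      list(c11 / detJ, (a13 * a32 - a12 * a33) / detJ,
           (a12 * a23 - a13 * a22) / detJ),
      list(c12 / detJ, (a11 * a33 - a13 * a31) / detJ,
           (a13 * a21 - a11 * a23) / detJ),
      list(c13 / detJ, (a12 * a31 - a11 * a32) / detJ,
           (a11 * a22 - a12 * a21) / detJ))
    nc <- length(detJ)
    g <- array(0, c(nc, 8, 3))
    for (a in 1:8) for (i in 1:3)
      g[, a, i] <- dN[a, 1] * inv[[1]][[i]] + dN[a, 2] * inv[[2]][[i]] +
                   dN[a, 3] * inv[[3]][[i]]
    out$gradN <- g
  }
  out
}

# exact volume of trilinear hexahedra (2x2x2 Gauss), vectorized over cells
.hex_volumes <- function(Xc) {
  v <- 0
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1))
    v <- v + .hex_geom_at(Xc, .gauss2 * c(sx, sy, sz), grad = FALSE)$detJ
  v
}

.cell_coord_list <- function(mesh) {
  lapply(1:3, function(i)
    matrix(mesh$vertices[mesh$cells, i], nrow = nrow(mesh$cells)))
}

# reference coordinates of SCVF quad corners and integration points
.box_ref <- local({
  rn <- .hex_ref_nodes
  fc <- t(vapply(.hex_faces, function(f) colMeans(rn[f, ]), numeric(3)))
  corners <- array(0, c(12, 4, 3))     # M, F1, C, F2
  ip <- matrix(0, 12, 3)
  for (e in 1:12) {
    M <- colMeans(rn[.hex_edges[e, ], ])
    F1 <- fc[.hex_edge_faces[e, 1], ]
    F2 <- fc[.hex_edge_faces[e, 2], ]
    corners[e, 1, ] <- M
    corners[e, 2, ] <- F1
    corners[e, 3, ] <- c(0, 0, 0)
    corners[e, 4, ] <- F2
    ip[e, ] <- (M + F1 + F2) / 4
  }
  Nip <- t(vapply(seq_len(12), function(e) .hex_shape(ip[e, ])$N, numeric(8)))
  list(corners = corners, ip = ip, Nip = Nip)
})
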