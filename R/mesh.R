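# Trilinear hexahedral meshes (VTK node ordering) with tagged boundary quads.

# Build a hex_mesh from tensor-product breaks and a keep mask over cells.
# tag_fun(centroid_matrix, axis, side) -> character tags for boundary facets.
.structured_hex_mesh <- function(xb, yb, zb, keep, tag_fun) {
  nx <- length(xb) - 1; ny <- length(yb) - 1; nz <- length(zb) - 1
  vid <- function(i, j, k) i + (length(xb)) * ((j - 1) + length(yb) * (k - 1))
  cell_idx <- which(keep, arr.ind = TRUE)  # (i,j,k) of kept cells
  i <- cell_idx[, 1]; j <- cell_idx[, 2]; k <- cell_idx[, 3]
  cells_full <- cbind(vid(i, j, k),     vid(i + 1, j, k),
                      vid(i + 1, j + 1, k), vid(i, j + 1, k),
                      vid(i, j, k + 1), vid(i + 1, j, k + 1),
                      vid(i + 1, j + 1, k + 1), vid(i, j + 1, k + 1))
  used <- sort(unique(as.vector(cells_full)))
  remap <- integer(length(xb) * length(yb) * length(zb))
  remap[used] <- seq_along(used)
  cells <- matrix(remap[cells_full], ncol = 8)
  gi <- (used - 1) %% length(xb) + 1
  gj <- ((used - 1) %/% length(xb)) %% length(yb) + 1
  gk <- (used - 1) %/% (length(xb) * length(yb)) + 1
  vertices <- cbind(xb[gi], yb[gj], zb[gk])

  # boundary facets: faces occurring exactly once
  nc <- nrow(cells)
  fv <- do.call(rbind, lapply(seq_along(.hex_faces), function(f)
    cbind(cell = seq_len(nc), face = f,
          matrix(cells[, .hex_faces[[f]]], ncol = 4))))
  key_m <- t(apply(fv[, 3:6, drop = FALSE], 1, sort))
  key <- paste(key_m[, 1], key_m[, 2], key_m[, 3], key_m[, 4])
  tab <- table(key)
  bidx <- which(key %in% names(tab)[tab == 1L])
  bf <- fv[bidx, , drop = FALSE]
  cent <- (vertices[bf[, 3], ] + vertices[bf[, 4], ] +
           vertices[bf[, 5], ] + vertices[bf[, 6], ]) / 4
  axis <- c(3, 3, 2, 1, 2, 1)[bf[, 2]]
  side <- c(-1, 1, -1, 1, 1, -1)[bf[, 2]]
  tags <- tag_fun(cent, axis, side)
  boundary <- data.frame(cell = bf[, 1], face = bf[, 2],
                         v1 = bf[, 3], v2 = bf[, 4],
                         v3 = bf[, 5], v4 = bf[, 6],
                         tag = tags, stringsAsFactors = FALSE)
  structure(list(vertices = vertices, cells = cells, boundary = boundary),
            class = "hex_mesh")
}

#' Structured hexahedral box mesh
#'
#' Uniform structured mesh of an axis-aligned box with `nx * ny * nz` cells.
#' Boundary facets are tagged by side; the default tags are
#' `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax` and can be renamed via
#' `tags` (e.g. to route boundary conditions).
#'
#' @param nx,ny,nz Cell counts per axis, >= 1.
#' @param dims Box extents \[m\], length 3.
#' @param origin Corner of the box \[m\], default the origin.
#' @param tags Named character vector renaming any of the six side tags.
#' @return A `hex_mesh`: vertices (n x 3), cells (n x 8, VTK node order),
#'   and a tagged boundary-facet table.
#' @export
#' @examples
#' m <- generate_box_mesh(2, 3, 4, dims = c(0.2, 0.3, 0.4))
#' nrow(m$cells)  # 24
generate_box_mesh <- function(nx, ny, nz, dims, origin = c(0, 0, 0),
                              tags = character()) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, all(dims > 0), length(dims) == 3)
  xb <- origin[1] + seq(0, dims[1], length.out = nx + 1)
  yb <- origin[2] + seq(0, dims[2], length.out = ny + 1)
  zb <- origin[3] + seq(0, dims[3], length.out = nz + 1)
  keep <- array(TRUE, c(nx, ny, nz))
  base <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  names(base) <- base
  base[names(tags)] <- tags
  tag_fun <- function(cent, axis, side) {
    nm <- paste0(c("x", "y", "z")[axis], ifelse(side < 0, "min", "max"))
    unname(base[nm])
  }
  .structured_hex_mesh(xb, yb, zb, keep, tag_fun)
}

#' Benchmark cylinder-with-cannula mesh
#'
#' Staircase (voxel-style) hexahedral mesh of a cylinder (default 40 mm
#' diameter, 30 mm height) with a coaxial cannula bore removed from the top
#' surface down to mid-height. The in-plane grid is graded: the two central
#' cell columns per axis match the bore half-width so the bore is resolved,
#' with uniform coarsening outward. At the default resolution
#' (`n_radial = 8`, `n_layers_half = 5`) the mesh has exactly 2540 hexahedral
#' cells.
#'
#' Boundary tags: `inlet` (bore tip at mid-height), `cannula_wall` (bore
#' sides), `outer_wall` (all external cylinder surfaces). The square
#' staircase bore has inlet area `(2 * bore_radius)^2`; the relative
#' difference to the circular bore section is returned in the
#' `staircase_tol` attribute.
#'
#' @param cyl_diameter,cyl_height Cylinder dimensions \[m\].
#' @param bore_radius Cannula bore inner radius \[m\].
#' @param n_radial Number of graded cell rings outward of the bore per side.
#' @param n_layers_half Number of cell layers per half height.
#' @return A `hex_mesh` with attributes `staircase_tol` (inlet-area relative
#'   error vs. the circular bore) and `volume_tol` (mesh-volume relative
#'   error vs. the exact cylinder-minus-bore volume).
#' @export
generate_benchmark_mesh <- function(cyl_diameter = 0.040, cyl_height = 0.030,
                                    bore_radius = 1.6e-3, n_radial = 8,
                                    n_layers_half = 5) {
  stopifnot(n_radial >= 1, n_layers_half >= 1)
  R <- cyl_diameter / 2
  H <- cyl_height
  rb <- bore_radius
  if (!(rb < R)) stop("bore must fit inside the cylinder", call. = FALSE)
  side <- rb + (R - rb) * seq_len(n_radial) / n_radial
  xb <- c(-rev(side), -rb, 0, rb, side)
  zb <- seq(0, H, length.out = 2 * n_layers_half + 1)
  nx <- length(xb) - 1
  nz <- length(zb) - 1
  cx <- (xb[-1] + xb[-length(xb)]) / 2
  cz <- (zb[-1] + zb[-length(zb)]) / 2
  in_circle <- outer(cx^2, cx^2, "+") < R^2
  in_bore_xy <- outer(abs(cx) < rb, abs(cx) < rb, "&")
  keep <- array(NA, c(nx, nx, nz))
  for (k in seq_len(nz))
    keep[, , k] <- in_circle & !(in_bore_xy & cz[k] > H / 2)
  tol <- 1e-9 * R
  tag_fun <- function(cent, axis, side) {
    tag <- rep("outer_wall", nrow(cent))
    inlet <- axis == 3 & side > 0 & abs(cent[, 3] - H / 2) < tol &
      abs(cent[, 1]) < rb & abs(cent[, 2]) < rb
    wall <- axis != 3 & cent[, 3] > H / 2 + tol &
      abs(cent[, 1]) < rb + tol & abs(cent[, 2]) < rb + tol &
      (abs(abs(cent[, 1]) - rb) < tol | abs(abs(cent[, 2]) - rb) < tol)
    tag[inlet] <- "inlet"
    tag[wall] <- "cannula_wall"
    tag
  }
  mesh <- .structured_hex_mesh(xb, xb, zb, keep, tag_fun)
  a_in <- (2 * rb)^2
  vol <- sum(.hex_volumes(.cell_coord_list(mesh)))
  vol_exact <- pi * R^2 * H - pi * rb^2 * H / 2
  attr(mesh, "staircase_tol") <- abs(a_in - pi * rb^2) / (pi * rb^2)
  attr(mesh, "volume_tol") <- abs(vol - vol_exact) / vol_exact
  attr(mesh, "geometry") <- list(R = R, H = H, bore_radius = rb)
  mesh
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d vertices, %d hexahedral cells, %d boundary facets\n",
              nrow(x$vertices), nrow(x$cells), nrow(x$boundary)))
  cat("  boundary tags:",
      paste(sprintf("%s (%d)", names(table(x$boundary$tag)),
                    table(x$boundary$tag)), collapse = ", "), "\n")
  invisible(x)
}

#' Total mesh volume
#'
#' Sum of exact trilinear cell volumes.
#' @param mesh A `hex_mesh`.
#' @return Volume \[m^3\].
#' @export
mesh_volume <- function(mesh) sum(.hex_volumes(.cell_coord_list(mesh)))
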