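#' Write mesh and nodal fields to a legacy-ASCII VTK file
#'
#' Unstructured-grid output loadable by ParaView/VisIt. Scalar fields are
#' numeric vectors of length `n_vertices`; a field given as an
#' `n_vertices x 3` matrix is written as a vector field (e.g. the solid
#' displacement).
#'
#' @param mesh A `hex_mesh`.
#' @param fields Named list of nodal fields (possibly empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields = list(), path) {
  stopifnot(inherits(mesh, "hex_mesh"))
  nv <- nrow(mesh$vertices)
  nc <- nrow(mesh$cells)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    n <- if (is.matrix(f)) nrow(f) else length(f)
    if (n != nv)
      stop(sprintf("field '%s' length does not match vertex count", nm),
           call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  fmt <- function(m) apply(format(m, digits = 9, scientific = TRUE,
                                  trim = TRUE), 1, paste, collapse = " ")
  wl("# vtk DataFile Version 3.0", "vertebropm field snapshot", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", nv))
  wl(fmt(mesh$vertices))
  wl(sprintf("CELLS %d %d", nc, 9 * nc))
  wl(fmt(cbind(8L, mesh$cells - 1L)))
  wl(sprintf("CELL_TYPES %d", nc))
  wl(as.character(rep(12L, nc)))
  if (length(fields)) {
    wl(sprintf("POINT_DATA %d", nv))
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        wl(sprintf("VECTORS %s double", nm))
        wl(fmt(f))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(format(f, digits = 9, scientific = TRUE, trim = TRUE))
      }
    }
  }
  invisible(path)
}

#' Read back points and point-data names from a legacy VTK file
#'
#' Minimal reader used for output verification: returns the vertex count,
#' cell count and the names of the point-data arrays.
#'
#' @param path VTK file written by [write_vtk()].
#' @return List with `n_points`, `n_cells`, `point_data` (character).
#' @export
read_vtk_info <- function(path) {
  lines <- readLines(path)
  np <- as.integer(sub("POINTS (\\d+).*", "\\1",
                       grep("^POINTS", lines, value = TRUE)[1]))
  ncl <- as.integer(sub("CELLS (\\d+).*", "\\1",
                        grep("^CELLS", lines, value = TRUE)[1]))
  nms <- c(sub("SCALARS (\\S+).*", "\\1",
               grep("^SCALARS", lines, value = TRUE)),
           sub("VECTORS (\\S+).*", "\\1",
               grep("^VECTORS", lines, value = TRUE)))
  list(n_points = np, n_cells = ncl, point_data = nms)
}
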