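#' Build a labelled structured mesh for a lung-bud geometry
#'
#' Discretizes the geometry on a cell-centred Cartesian grid. The axial
#' coordinate is stored in mapped form (xi = y / L) so that the same grid
#' supports axially growing domains; for a fixed domain y = xi * L0. Each
#' cell carries one subdomain label: 1 lumen, 2 epithelium, 3 mesenchyme,
#' 4 interstitium/buffer.
#'
#' @param geometry A [lung_geometry()].
#' @param hmax Target maximum cell size (dimensionless). The number of cells
#'   grows as \code{hmax} decreases.
#' @param final_height Optional final domain height for growth runs; the axial
#'   resolution is chosen so cells are no larger than \code{hmax} at that
#'   height (hence finer initially).
#' @return An object of class \code{lung_mesh} with fields \code{x} (cell
#'   centre abscissae), \code{y} (initial cell centre heights), \code{labels}
#'   (Nx x Ny integer matrix), \code{hx}, \code{Ny}, \code{L0} (initial total
#'   height), \code{h_stalk} and the generating geometry.
#' @examples
#' m <- make_mesh(lung_geometry(), hmax = 0.2)
#' table(m$labels)
#' @export
make_mesh <- function(geometry, hmax = 0.2, final_height = NULL) {
  stopifnot(inherits(geometry, "lung_geometry"))
  if (!(hmax > 0)) stop("hmax must be > 0", call. = FALSE)
  g <- geometry
  h_stalk <- effective_stalk(g)
  half_w <- g$Rc * g$tip_mesenchyme_scale + g$Lfar
  L0 <- h_stalk + g$Rc * g$tip_mesenchyme_scale + g$Lfar
  Ltarget <- max(L0, if (is.null(final_height)) 0 else final_height)
  Nx <- max(8L, as.integer(ceiling(2 * half_w / hmax)))
  Ny <- max(8L, as.integer(ceiling(Ltarget / hmax)))
  hx <- 2 * half_w / Nx
  x <- -half_w + (seq_len(Nx) - 0.5) * hx
  y <- (seq_len(Ny) - 0.5) / Ny * L0
  labels <- rd_labels(x, y, h_stalk, geom_clist(g))
  structure(list(x = x, y = y, hx = hx, Ny = Ny, Nx = Nx,
                 L0 = L0, h_stalk = h_stalk, hmax = hmax,
                 labels = labels, geometry = g),
            class = "lung_mesh")
}

#' @export
print.lung_mesh <- function(x, ...) {
  cat(sprintf("Structured lung-bud mesh: %d x %d cells (hx = %.3g, hy = %.3g), height %g\n",
              x$Nx, x$Ny, x$hx, x$L0 / x$Ny, x$L0))
  tab <- table(factor(x$labels, levels = 1:4,
                      labels = c("lumen", "epithelium", "mesenchyme", "buffer")))
  print(tab)
  invisible(x)
}

#' Per-subdomain areas of a mesh
#'
#' Sums cell areas per label; converges to [geometry_areas()] as
#' \code{hmax} decreases (the buffer soaks up the remainder of the bounding
#' box).
#'
#' @param mesh A [make_mesh()] result.
#' @return Named numeric vector of areas for labels 1..4.
#' @export
mesh_areas <- function(mesh) {
  cell <- mesh$hx * mesh$L0 / mesh$Ny
  a <- vapply(1:4, function(l) sum(mesh$labels == l) * cell, 0)
  names(a) <- c("lumen", "epithelium", "mesenchyme", "buffer")
  a
}

#' Cell centres and labels as a data.frame
#'
#' @param mesh A [make_mesh()] result.
#' @param L Domain height for the axial coordinate (defaults to initial).
#' @return data.frame with x, y, label per cell (column-major cell order).
#' @export
mesh_cells <- function(mesh, L = mesh$L0) {
  xi <- (seq_len(mesh$Ny) - 0.5) / mesh$Ny
  data.frame(x = rep(mesh$x, mesh$Ny),
             y = rep(xi * L, each = mesh$Nx),
             label = as.vector(mesh$labels))
}

#' Write a mesh (with optional cell fields) as a legacy VTK file
#'
#' Emits an ASCII legacy-VTK \code{STRUCTURED_POINTS}-style rectilinear
#' description with the subdomain label and any supplied nodal fields as cell
#' data, readable by ParaView and by [read_field_vtk()].
#'
#' @param mesh A [make_mesh()] result.
#' @param file Output path.
#' @param fields Optional named list of per-cell vectors (length Nx * Ny).
#' @param L Domain height for the axial coordinate (defaults to the mesh's).
#' @return \code{file}, invisibly.
#' @export
write_field_vtk <- function(mesh, file, fields = list(), L = mesh$L0) {
  con <- file(file, "w")
  on.exit(close(con))
  nx <- mesh$Nx; ny <- mesh$Ny
  writeLines(c("# vtk DataFile Version 3.0",
               "lung bud reaction-diffusion fields", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", nx, ny)), con)
  writeLines(sprintf("X_COORDINATES %d double", nx), con)
  writeLines(paste(format(mesh$x, digits = 10), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", ny), con)
  xi <- (seq_len(ny) - 0.5) / ny
  writeLines(paste(format(xi * L, digits = 10), collapse = " "), con)
  writeLines(c("Z_COORDINATES 1 double", "0"), con)
  writeLines(sprintf("POINT_DATA %d", nx * ny), con)
  writeLines(c("SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(mesh$labels), collapse = " "), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 10), collapse = " "), con)
  }
  invisible(file)
}

#' Read back a VTK file written by [write_field_vtk()]
#'
#' @param file Path to a legacy-VTK rectilinear file.
#' @return List with \code{x}, \code{y}, \code{label} matrix and one matrix
#'   per stored field.
#' @export
read_field_vtk <- function(file) {
  ln <- readLines(file)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", ln, value = TRUE), " ")[[1]][2:3])
  nx <- dims[1]; ny <- dims[2]
  grab_after <- function(pat) {
    i <- grep(pat, ln)[1]
    as.numeric(strsplit(trimws(ln[i + 1]), "\\s+")[[1]])
  }
  x <- grab_after("^X_COORDINATES")
  y <- grab_after("^Y_COORDINATES")
  out <- list(x = x, y = y)
  sc <- grep("^SCALARS", ln)
  for (i in sc) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    vals <- as.numeric(strsplit(trimws(ln[i + 2]), "\\s+")[[1]])
    out[[nm]] <- matrix(vals, nx, ny)
  }
  out$label <- matrix(as.integer(out$label), nx, ny)
  out
}
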