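# Structured graded axisymmetric meshes for the idealised craniectomy domain.
#
# The domain is the rectangle [0, cyl_radius] x [0, cyl_height] in (r, z).
# The mesh is a tensor product of two graded 1-D subdivisions, refined towards
# the craniectomy edge (a_c, cyl_height): biquadratic (9-node) displacement
# elements sharing corner nodes with bilinear (4-node) pressure elements
# (a Taylor-Hood pair, inf-sup stable for the mixed Biot problem).

#' Idealised craniectomy geometry
#'
#' Cylinder of gel confined by rigid walls, loaded by a rigid platen with a
#' circular opening of radius `a_c`; `R_f` is the fillet/transition radius
#' softening the opening edge.  `a_c = 0` is allowed and means the platen
#' covers the whole top face (used for patch tests and column verification).
#'
#' @param cyl_radius,cyl_height cylinder radius and height, mm.
#' @param a_c craniectomy opening radius, mm, `0 <= a_c < cyl_radius`.
#' @param R_f fillet radius, mm, `0 <= R_f < cyl_radius - a_c`.
#' @return Object of class `craniectomy_geometry`.
#' @export
craniectomy_geometry <- function(cyl_radius, cyl_height, a_c, R_f = 0) {
  stopifnot(cyl_radius > 0, cyl_height > 0)
  if (!(a_c >= 0 && a_c < cyl_radius))
    stop("need 0 <= a_c < cyl_radius")
  if (!(R_f >= 0 && R_f < cyl_radius - a_c))
    stop("need 0 <= R_f < cyl_radius - a_c")
  structure(list(cyl_radius = cyl_radius, cyl_height = cyl_height,
                 a_c = a_c, R_f = R_f),
            class = "craniectomy_geometry")
}

#' @export
print.craniectomy_geometry <- function(x, ...) {
  cat(sprintf("Craniectomy geometry: cylinder R = %g mm, H = %g mm; a_c = %g mm, R_f = %g mm\n",
              x$cyl_radius, x$cyl_height, x$a_c, x$R_f))
  invisible(x)
}

# Graded 1-D subdivision of [0, L]: cells of size `fine` within `band` of the
# focus x0, growing geometrically (factor `ratio`) to at most `far` outside.
graded_breaks <- function(L, x0, fine, far, band = 0, ratio = 1.5) {
  stopifnot(L > 0, fine > 0, far >= fine)
  x0 <- min(max(x0, 0), L)
  walk <- function(dist) {
    if (dist <= 1e-12) return(numeric())
    sizes <- numeric(); pos <- 0; s <- fine
    while (pos < dist - 1e-9) {
      use <- if (pos < band - 1e-9) fine else { s <- min(s * ratio, far); s }
      use <- min(use, dist - pos)
      sizes <- c(sizes, use); pos <- pos + use
    }
    n <- length(sizes)
    if (n >= 2 && sizes[n] < 0.35 * sizes[n - 1]) {
      sizes[n - 1] <- sizes[n - 1] + sizes[n]
      sizes <- sizes[-n]
    }
    cumsum(sizes)
  }
  brk <- sort(unique(round(c(0, x0 - rev(walk(x0)), x0, x0 + walk(L - x0), L), 9)))
  brk[brk >= 0 & brk <= L]
}

#' Build a graded axisymmetric craniectomy mesh
#'
#' Structured quadrilateral mesh of the (r, z) rectangle, refined towards the
#' craniectomy edge: element size at most `refinement$fine` within a band of
#' `2 R_f` (or 2 mm when `R_f = 0`) of the point `(a_c, cyl_height)`, growing
#' geometrically to `refinement$far` elsewhere.  Displacement nodes are the
#' biquadratic grid, pressure nodes the corner grid.
#'
#' @param geometry a [craniectomy_geometry()].
#' @param refinement list with `fine` and `far` element sizes, mm
#'   (`fine <= far`).
#' @return Object of class `aximesh`: break vectors `rb`, `zb`, element
#'   counts `nr`, `nz`, displacement-node coordinate vectors `ru`, `zu`,
#'   node/element counts, and the geometry.
#' @export
build_dc_mesh <- function(geometry, refinement = list(fine = 1.5, far = 6)) {
  stopifnot(inherits(geometry, "craniectomy_geometry"),
            refinement$fine > 0, refinement$fine <= refinement$far)
  R <- geometry$cyl_radius; H <- geometry$cyl_height
  # fine band at least 2 R_f wide, with a floor so meshes stay comparable
  # across a fillet sweep (the reaction near the edge is what the band must
  # resolve, whatever R_f is)
  band <- max(2 * geometry$R_f, 6 * refinement$fine, 2)
  focus_r <- if (geometry$a_c > 0) geometry$a_c else 0
  rb <- graded_breaks(R, focus_r, refinement$fine, refinement$far, band = band)
  zb <- graded_breaks(H, H, refinement$fine, refinement$far, band = band)
  if (geometry$a_c > 0 && sum(rb < geometry$a_c - 1e-9) < 4)
    stop("refinement too coarse to resolve the craniectomy opening: ",
         "fewer than 4 elements across r < a_c")
  nr <- length(rb) - 1; nz <- length(zb) - 1
  if (nr < 2 || nz < 2) stop("mesh needs at least 2 elements in each direction")
  # displacement node coordinates: corners + midpoints
  mid <- function(b) { v <- numeric(2 * length(b) - 1)
    v[seq(1, length(v), 2)] <- b
    v[seq(2, length(v), 2)] <- (b[-1] + b[-length(b)]) / 2
    v }
  ru <- mid(rb); zu <- mid(zb)
  structure(list(rb = rb, zb = zb, nr = nr, nz = nz, ru = ru, zu = zu,
                 n_unodes = length(ru) * length(zu),
                 n_pnodes = length(rb) * length(zb),
                 n_elem = nr * nz, geometry = geometry,
                 refinement = refinement),
            class = "aximesh")
}

#' @export
print.aximesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d x %d = %d elements\n", x$nr, x$nz, x$n_elem))
  cat(sprintf("  %d displacement nodes (biquadratic), %d pressure nodes (bilinear)\n",
              x$n_unodes, x$n_pnodes))
  cat(sprintf("  element sizes: r in [%.3g, %.3g] mm, z in [%.3g, %.3g] mm\n",
              min(diff(x$rb)), max(diff(x$rb)), min(diff(x$zb)), max(diff(x$zb))))
  invisible(x)
}

# Index of displacement node (i over r, j over z), column-major over the grid.
unode_index <- function(mesh, i, j) (j - 1L) * length(mesh$ru) + i
# Index of pressure (corner) node.
pnode_index <- function(mesh, i, j) (j - 1L) * length(mesh$rb) + i

# Displacement node indices of element (er, ez), local tensor order
# (a over xi, b over eta), length 9.
elem_unodes <- function(mesh, er, ez) {
  i0 <- 2L * (er - 1L); j0 <- 2L * (ez - 1L)
  idx <- integer(9)
  for (b in 1:3) for (a in 1:3)
    idx[(b - 1L) * 3L + a] <- unode_index(mesh, i0 + a, j0 + b)
  idx
}

# Pressure node indices of element (er, ez), length 4.
elem_pnodes <- function(mesh, er, ez) {
  idx <- integer(4)
  for (b in 1:2) for (a in 1:2)
    idx[(b - 1L) * 2L + a] <- pnode_index(mesh, er + a - 1L, ez + b - 1L)
  idx
}

#' Per-element Jacobian determinants of a mesh
#'
#' For the tensor-product mesh the mapping of each element is affine with
#' constant Jacobian determinant `(dr/2)(dz/2)`; all must be positive
#' (no inverted elements).
#'
#' @param mesh an `aximesh`.
#' @return Numeric vector of length `n_elem`.
#' @export
mesh_jacobians <- function(mesh) {
  stopifnot(inherits(mesh, "aximesh"))
  as.vector(outer(diff(mesh$rb) / 2, diff(mesh$zb) / 2))
}

#' Export a mesh in legacy VTK unstructured-grid format
#'
#' Writes the corner-node quadrilateral mesh (pressure grid) as an ASCII VTK
#' file, a lowest-common-denominator exchange format readable by ParaView
#' and meshio.
#'
#' @param mesh an `aximesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "aximesh"))
  nrp <- length(mesh$rb); nzp <- length(mesh$zb)
  pts <- cbind(rep(mesh$rb, nzp), rep(mesh$zb, each = nrp), 0)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "dcpve axisymmetric mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  cells <- matrix(NA_integer_, mesh$n_elem, 5)
  e <- 0L
  for (ez in seq_len(mesh$nz)) for (er in seq_len(mesh$nr)) {
    e <- e + 1L
    p <- elem_pnodes(mesh, er, ez) - 1L   # VTK is 0-based; quad order ccw
    cells[e, ] <- c(4L, p[1], p[2], p[4], p[3])
  }
  writeLines(sprintf("CELLS %d %d", mesh$n_elem, 5L * mesh$n_elem), con)
  utils::write.table(cells, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", mesh$n_elem), con)
  writeLines(as.character(rep(9L, mesh$n_elem)), con)
  invisible(path)
}
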