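# The (cQ, cTew) coupling plane: projections of trajectories onto the
# plane spanned by the dominant quaternary mode and the ensemble-weighted
# tertiary coupling mode, an equidistant grid over the projections,
# backprojection of grid points to full structures, and the L-shaped
# cQ -> cTew path used for the contact analysis.
#
# Backprojection is linear (origin + a*cQ + b*cTew) and therefore ignores
# the curvature of finite rigid-body rotations; backprojected structures
# are low-dimensional representatives, not physical conformations.

#' Project a trajectory onto the (cQ, cTew) plane
#'
#' @param traj A `qt_trajectory` (raw frames, globally fitted to the
#'   origin's frame of reference).
#' @param cQ,cTew `collective_mode`s spanning the plane; they must be
#'   near-orthogonal (an absolute scalar product >= 0.5 is an error).
#' @param origin A `structure_frame` serving as plane origin, typically the
#'   T-state reference.
#' @param anchors Optional named list of `structure_frame`s (e.g.
#'   `list(T = ..., R = ...)`) whose plane coordinates are recorded.
#' @return Object of class `qt_plane`: `points` (F x 2 matrix of (a, b) in
#'   nm), `anchors` (named 2-column matrix or NULL), plus the modes and
#'   origin used.
#' @export
project_plane <- function(traj, cQ, cTew, origin, anchors = NULL) {
  ov <- mode_overlap(cQ, cTew)
  if (ov >= 0.5)
    stop(sprintf("plane ill-defined: |cQ . cTew| = %.2f >= 0.5", ov))
  ca <- collective_mode(cQ$vector, cQ$role, origin = origin$xyz)
  cb <- collective_mode(cTew$vector, cTew$role, origin = origin$xyz)
  pts <- cbind(a = project_mode(traj, ca), b = project_mode(traj, cb))
  anc <- NULL
  if (!is.null(anchors)) {
    anc <- t(vapply(anchors, function(fr)
      c(project_mode(fr, ca), project_mode(fr, cb)), numeric(2)))
    colnames(anc) <- c("a", "b")
  }
  structure(list(points = pts, anchors = anc, cQ = ca, cTew = cb,
                 origin = origin),
            class = "qt_plane")
}

#' Equidistant grid over a plane projection
#'
#' The span between minimal and maximal projections (extended to cover any
#' anchors) is divided equidistantly into `n_per_axis` parts per axis; cell
#' centres sit at the middle of each part, so every projected frame falls
#' inside the grid bounds.
#'
#' @param plane A `qt_plane`.
#' @param n_per_axis Number of divisions per axis (default 20, giving a
#'   20 x 20 = 400-cell grid).
#' @return Object of class `qt_grid`: `n`, `centers_a`, `centers_b`,
#'   `bounds` (2 x 2: rows min/max, cols a/b), `h` (cell sizes), and the
#'   plane.
#' @export
build_grid <- function(plane, n_per_axis = 20L) {
  pts <- plane$points
  if (!is.null(plane$anchors)) pts <- rbind(pts, plane$anchors)
  lo <- apply(pts, 2L, min)
  hi <- apply(pts, 2L, max)
  if (any(hi - lo <= 0)) stop("degenerate axis: zero projection range")
  h <- (hi - lo) / n_per_axis
  centers_a <- lo[1] + (seq_len(n_per_axis) - 0.5) * h[1]
  centers_b <- lo[2] + (seq_len(n_per_axis) - 0.5) * h[2]
  structure(list(n = as.integer(n_per_axis), centers_a = centers_a,
                 centers_b = centers_b,
                 bounds = rbind(min = lo, max = hi), h = h, plane = plane),
            class = "qt_grid")
}

#' @export
print.qt_grid <- function(x, ...) {
  cat(sprintf("qt_grid: %d x %d cells over a [%.3f, %.3f] b [%.3f, %.3f] nm\n",
              x$n, x$n, x$bounds[1, 1], x$bounds[2, 1], x$bounds[1, 2],
              x$bounds[2, 2]))
  invisible(x)
}

#' Grid cell containing a plane point
#'
#' @param grid A `qt_grid`.
#' @param point Length-2 plane coordinate (a, b).
#' @return Integer (i, j) cell indices, clamped to the grid.
#' @export
cell_of <- function(grid, point) {
  lo <- grid$bounds["min", ]
  ij <- ceiling((point - lo) / grid$h)
  pmin(pmax(as.integer(ij), 1L), grid$n)
}

#' Backproject a plane coordinate to a full structure
#'
#' coords = origin + a * cQ + b * cTew; the structure lies exactly in the
#' two-dimensional coupling plane.
#'
#' @param ab Length-2 plane coordinate (a, b) in nm.
#' @param origin A `structure_frame` (plane origin).
#' @param cQ,cTew Normalised `collective_mode`s.
#' @return A `structure_frame` with provenance `backprojected`.
#' @export
backproject <- function(ab, origin, cQ, cTew) {
  structure_frame(origin$xyz + ab[1] * cQ$vector + ab[2] * cTew$vector,
                  origin$atoms, origin$partition,
                  provenance = "backprojected")
}

#' Backprojected structures for every grid cell
#'
#' @param grid A `qt_grid`.
#' @return List of `structure_frame`s of length n^2, ordered with the a
#'   index varying fastest (column-major in (i, j)); carries a `dim`
#'   attribute `c(n, n)`.
#' @export
grid_structures <- function(grid) {
  pl <- grid$plane
  out <- vector("list", grid$n^2)
  k <- 0L
  for (j in seq_len(grid$n)) {
    for (i in seq_len(grid$n)) {
      k <- k + 1L
      out[[k]] <- backproject(c(grid$centers_a[i], grid$centers_b[j]),
                              pl$origin, pl$cQ, pl$cTew)
    }
  }
  attr(out, "dim_grid") <- c(grid$n, grid$n)
  out
}

#' L-shaped path through the grid (cQ leg first, then cTew leg)
#'
#' Starting from `start_cell`, the path first varies the cQ (a) index to
#' the end cell's a index, then the cTew (b) index, visiting
#' |di| + |dj| + 1 cells; each cell, including the corner, appears exactly
#' once. Cell-centre structures are backprojected for every cell.
#'
#' @param grid A `qt_grid`.
#' @param start_cell,end_cell Integer (i, j) cell indices, e.g. the cells
#'   containing the T- and R-state projections (see [cell_of()]).
#' @return Object of class `qt_path`: `cells` (L x 2 integer matrix),
#'   `coords` (L x 2 plane coordinates), `corner` (index of the turning
#'   cell), `structures` (list of backprojected `structure_frame`s), and
#'   the grid.
#' @export
make_path <- function(grid, start_cell, end_cell) {
  s <- as.integer(start_cell)
  e <- as.integer(end_cell)
  if (any(c(s, e) < 1L) || any(c(s, e) > grid$n))
    stop("path endpoints outside the grid")
  leg1 <- if (s[1] == e[1]) s[1] else seq(s[1], e[1])
  leg2 <- if (s[2] == e[2]) integer(0) else seq(s[2], e[2])[-1L]
  cells <- rbind(cbind(leg1, s[2]),
                 if (length(leg2)) cbind(e[1], leg2))
  dimnames(cells) <- list(NULL, c("i", "j"))
  coords <- cbind(a = grid$centers_a[cells[, 1]],
                  b = grid$centers_b[cells[, 2]])
  pl <- grid$plane
  structures <- lapply(seq_len(nrow(cells)), function(k)
    backproject(coords[k, ], pl$origin, pl$cQ, pl$cTew))
  structure(list(cells = cells, coords = coords, corner = length(leg1),
                 structures = structures, grid = grid),
            class = "qt_path")
}

#' @export
print.qt_path <- function(x, ...) {
  cat(sprintf("qt_path: %d cells (corner at %d)\n", nrow(x$cells), x$corner))
  invisible(x)
}

#' Path between the anchor (T/R) cells of a grid
#'
#' Convenience wrapper: builds the cQ -> cTew path from the cell containing
#' the first anchor to the cell containing the second.
#'
#' @param grid A `qt_grid` whose plane carries at least two anchors.
#' @return A `qt_path`.
#' @export
anchor_path <- function(grid) {
  anc <- grid$plane$anchors
  if (is.null(anc) || nrow(anc) < 2L)
    stop("grid's plane carries fewer than two anchors")
  make_path(grid, cell_of(grid, anc[1, ]), cell_of(grid, anc[2, ]))
}
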