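# Core data model: atom tables, structure frames, chain partitions,
# trajectories, and rigid-body superposition kernels.
#
# Conventions: all lengths in nm. Coordinates of one conformation are a
# flat numeric vector of length 3N ordered (x1, y1, z1, x2, ...), matching
# the bio3d xyz layout; a trajectory stores an F x 3N matrix with one row
# per frame.

#' Convert between flat xyz vectors and N x 3 coordinate matrices
#'
#' @param xyz Numeric vector of length 3N (order x1, y1, z1, x2, ...).
#' @param mat Numeric N x 3 matrix.
#' @return `xyz_mat()` returns an N x 3 matrix; `xyz_vec()` the flat vector.
#' @export
xyz_mat <- function(xyz) {
  stopifnot(length(xyz) %% 3 == 0)
  matrix(xyz, ncol = 3L, byrow = TRUE)
}

#' @rdname xyz_mat
#' @export
xyz_vec <- function(mat) as.numeric(t(mat))

#' Build an atom table
#'
#' Minimal per-atom metadata used throughout the package. Radii and masses
#' are filled from the element tables when not supplied.
#'
#' @param element Character vector of element symbols (e.g. "C", "FE").
#' @param chain Character vector of chain identifiers.
#' @param resno Integer residue numbers.
#' @param resid Character residue names (default "ALA").
#' @param name Atom names (default element symbols).
#' @param radius Per-atom van der Waals radii in nm; looked up from `radii`
#'   when `NULL`.
#' @param mass Atomic masses in u; looked up when `NULL`.
#' @param radii Named element-to-radius table, see [default_radii()].
#' @return A data.frame with columns name, resid, chain, resno, element,
#'   radius, mass.
#' @export
atom_table <- function(element, chain, resno, resid = "ALA",
                       name = element, radius = NULL, mass = NULL,
                       radii = default_radii()) {
  n <- max(length(element), length(chain), length(resno))
  element <- toupper(trimws(rep_len(element, n)))
  if (is.null(radius)) radius <- .element_lookup(element, radii, "radius")
  if (is.null(mass)) mass <- .element_lookup(element, .default_masses, "mass")
  if (any(radius <= 0)) stop("all vdW radii must be positive")
  data.frame(name = rep_len(name, n), resid = rep_len(resid, n),
             chain = rep_len(chain, n), resno = rep_len(resno, n),
             element = element, radius = radius, mass = rep_len(mass, n),
             stringsAsFactors = FALSE)
}

#' Chain partition of an atom table
#'
#' A partition is an ordered, named list of disjoint atom-index vectors
#' covering all atoms; by default one group per chain identifier. Any other
#' grouping (e.g. two dimers, or domains within one chain) can be supplied
#' wherever a partition is accepted.
#'
#' @param atoms Atom table (see [atom_table()]), or a `structure_frame`.
#' @return Named list of integer index vectors.
#' @export
chain_partition <- function(atoms) {
  if (inherits(atoms, "structure_frame") || inherits(atoms, "qt_trajectory"))
    atoms <- atoms$atoms
  ids <- unique(atoms$chain)
  out <- lapply(ids, function(ch) which(atoms$chain == ch))
  names(out) <- as.character(ids)
  out
}

.check_partition <- function(partition, n_atoms) {
  idx <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(idx)) stop("partition groups are not disjoint")
  if (length(idx) != n_atoms || !setequal(idx, seq_len(n_atoms)))
    stop("partition must cover every atom exactly once")
  invisible(partition)
}

#' Construct a structure frame (one conformation)
#'
#' @param xyz Flat coordinate vector (3N, nm) or N x 3 matrix.
#' @param atoms Atom table, one row per atom.
#' @param partition Chain partition; defaults to one group per chain.
#' @param provenance Label: one of raw, tertiary_only, quaternary_only,
#'   synthetic, backprojected, reference.
#' @return Object of class `structure_frame` with elements xyz, atoms,
#'   partition, provenance.
#' @export
structure_frame <- function(xyz, atoms, partition = NULL,
                            provenance = "raw") {
  if (is.matrix(xyz)) xyz <- xyz_vec(xyz)
  xyz <- as.numeric(xyz)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  n <- length(xyz) / 3L
  if (n != nrow(atoms)) stop("coordinate / atom table length mismatch")
  if (is.null(partition)) partition <- chain_partition(atoms)
  .check_partition(partition, n)
  structure(list(xyz = xyz, atoms = atoms, partition = partition,
                 provenance = provenance),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d group(s) [%s]\n",
              nrow(x$atoms), length(x$partition), x$provenance))
  invisible(x)
}

#' Number of atoms in a frame or trajectory
#' @param x A `structure_frame` or `qt_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Construct a trajectory
#'
#' @param xyz F x 3N matrix of coordinates in nm (one row per frame), or a
#'   list of flat xyz vectors.
#' @param atoms Shared atom table.
#' @param partition Chain partition (default per-chain).
#' @param times Optional frame times in ns.
#' @param provenance Label as in [structure_frame()].
#' @return Object of class `qt_trajectory`.
#' @export
trajectory <- function(xyz, atoms, partition = NULL, times = NULL,
                       provenance = "raw") {
  if (is.list(xyz)) xyz <- do.call(rbind, xyz)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("trajectory width must equal 3 x atom count")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(partition)) partition <- chain_partition(atoms)
  .check_partition(partition, nrow(atoms))
  if (!is.null(times) && length(times) != nrow(xyz))
    stop("times must have one entry per frame")
  structure(list(xyz = xyz, atoms = atoms, partition = partition,
                 times = times, provenance = provenance),
            class = "qt_trajectory")
}

#' @export
print.qt_trajectory <- function(x, ...) {
  cat(sprintf("qt_trajectory: %d frames x %d atoms [%s]\n",
              nrow(x$xyz), nrow(x$atoms), x$provenance))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `qt_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure frame
#'
#' @param traj A `qt_trajectory`.
#' @param i Frame index (1-based).
#' @return A `structure_frame`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  structure_frame(traj$xyz[i, ], traj$atoms, traj$partition,
                  provenance = traj$provenance)
}

#' Rigid-body transform
#'
#' A proper rotation plus translation, acting on column 3-vectors as
#' x -> R x + t.
#'
#' @param rotation 3 x 3 proper orthonormal matrix (det = +1).
#' @param translation Length-3 vector in nm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Invert or compose rigid transforms
#'
#' @param tf,tf1,tf2 `rigid_transform` objects.
#' @return A `rigid_transform`; `compose_transform` returns the map
#'   applying `tf2` first, then `tf1`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation),
                  -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' @rdname invert_transform
#' @export
compose_transform <- function(tf1, tf2) {
  rigid_transform(tf1$rotation %*% tf2$rotation,
                  as.numeric(tf1$rotation %*% tf2$translation) +
                    tf1$translation)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of `mobile` mapped onto `target`. The reflection branch of
#' the SVD solution is never returned.
#'
#' @param mobile,target N x 3 coordinate matrices (or flat 3N vectors) over
#'   the same N >= 3 non-collinear points.
#' @param weights Optional per-atom nonnegative weights (not all zero);
#'   uniform weighting when `NULL`.
#' @return A `rigid_transform` mapping mobile onto target.
#' @export
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' tf <- kabsch_fit(x, x)          # identity
#' max(abs(tf$rotation - diag(3)))
kabsch_fit <- function(mobile, target, weights = NULL) {
  if (!is.matrix(mobile)) mobile <- xyz_mat(mobile)
  if (!is.matrix(target)) target <- xyz_mat(target)
  n <- nrow(mobile)
  if (nrow(target) != n) stop("point sets differ in size")
  if (n < 3L) stop("at least 3 points are required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative, length N, not all zero")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  xm <- sweep(mobile, 2L, cm)
  xt <- sweep(target, 2L, ct)
  h <- crossprod(xm * w, xt)                 # sum_i w_i x_i y_i^T
  sv <- svd(h)
  # collinear or coincident points leave the rotation underdetermined
  scale <- sum(w * rowSums(xm^2)) + sum(w * rowSums(xt^2))
  if (sv$d[2] <= 1e-12 * max(sv$d[1], scale, .Machine$double.eps))
    stop("degenerate (collinear or coincident) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u) # column convention: y = R x + t
  rigid_transform(r, ct - as.numeric(r %*% cm))
}

#' Apply a rigid transform to (a subset of) coordinates
#'
#' Atoms outside `subset` are left unchanged.
#'
#' @param xyz Flat 3N coordinate vector or N x 3 matrix.
#' @param tf A `rigid_transform`.
#' @param subset Atom indices to transform; all atoms when `NULL`.
#' @return Coordinates in the same shape as the input.
#' @export
apply_transform <- function(xyz, tf, subset = NULL) {
  flat <- !is.matrix(xyz)
  mat <- if (flat) xyz_mat(xyz) else xyz
  if (is.null(subset)) subset <- seq_len(nrow(mat))
  if (length(subset) == 0L) stop("subset must be non-empty")
  mat[subset, ] <- sweep(mat[subset, , drop = FALSE] %*% t(tf$rotation),
                         2L, tf$translation, "+")
  if (flat) xyz_vec(mat) else mat
}

#' Weighted RMSD between two coordinate sets
#'
#' @param a,b Flat 3N vectors or N x 3 matrices.
#' @param weights Optional per-atom weights.
#' @return RMSD in nm.
#' @export
coord_rmsd <- function(a, b, weights = NULL) {
  if (!is.matrix(a)) a <- xyz_mat(a)
  if (!is.matrix(b)) b <- xyz_mat(b)
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Orthonormal rigid-body basis of a chain
#'
#' Returns, for each partition group, six orthonormal 3N-vectors supported
#' on that group's atoms: three uniform translations and three infinitesimal
#' rotations about the group centroid (orthonormalised). These span the
#' rigid-body degrees of freedom removed by per-chain superposition and are
#' used to test tertiary/quaternary orthogonality and to project internal
#' (rigid-free) directions.
#'
#' @param frame A `structure_frame` (geometry at which rotations are
#'   linearised).
#' @param partition Chain partition (default the frame's).
#' @return 3N x (6 * n_groups) matrix of orthonormal columns, grouped by
#'   chain.
#' @export
rigid_basis <- function(frame, partition = frame$partition) {
  n <- n_atoms(frame)
  mat <- xyz_mat(frame$xyz)
  out <- matrix(0, nrow = 3L * n, ncol = 6L * length(partition))
  col <- 0L
  for (idx in partition) {
    cen <- colMeans(mat[idx, , drop = FALSE])
    rel <- sweep(mat[idx, , drop = FALSE], 2L, cen)
    block <- matrix(0, nrow = 3L * n, ncol = 6L)
    rows <- as.vector(t(outer(idx, c(1L, 2L, 3L), function(i, k) 3L * (i - 1L) + k)))
    for (ax in 1:3) {                         # translations
      v <- matrix(0, nrow = length(idx), ncol = 3L)
      v[, ax] <- 1
      block[rows, ax] <- as.vector(t(v))
    }
    axes <- diag(3)
    for (ax in 1:3) {                         # infinitesimal rotations
      v <- t(apply(rel, 1L, function(p) .cross3(axes[ax, ], p)))
      block[rows, 3L + ax] <- as.vector(t(v))
    }
    q <- qr.Q(qr(block[rows, , drop = FALSE])) # orthonormalise within chain
    block[rows, ] <- q[, 1:6]
    out[, col + 1:6] <- block
    col <- col + 6L
  }
  out
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Project the per-chain rigid-body content out of a 3N displacement vector,
# leaving a purely internal (tertiary) direction.
.project_internal <- function(v, frame, partition = frame$partition) {
  b <- rigid_basis(frame, partition)
  v - b %*% crossprod(b, v)
}

#' Count heavy (non-hydrogen) atoms under a selection policy
#'
#' The default policy, `"protein_prosthetic"`, counts protein and
#' prosthetic-group (e.g. heme) atoms and excludes solvent and monoatomic
#' ions by residue name; `"all"` counts every non-hydrogen atom.
#'
#' @param frame A `structure_frame` (or atom table).
#' @param policy Selection policy.
#' @return Integer count of non-hydrogen atoms in the selection.
#' @export
count_heavy_atoms <- function(frame,
                              policy = c("protein_prosthetic", "all")) {
  policy <- match.arg(policy)
  atoms <- if (inherits(frame, "structure_frame")) frame$atoms else frame
  ele <- toupper(trimws(atoms$element))
  known <- unique(c(names(.default_radii), names(.default_masses)))
  if (any(!ele %in% known)) {
    bad <- which(!ele %in% known)
    stop(sprintf("unknown element symbol(s) %s at atom(s) %s",
                 paste(unique(ele[bad]), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  keep <- !(ele %in% c("H", "D"))
  if (policy == "protein_prosthetic") {
    res <- toupper(trimws(atoms$resid))
    keep <- keep & !(res %in% .solvent_resids) & !(res %in% .ion_resids)
  }
  sum(keep)
}
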