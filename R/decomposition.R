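# Orthogonal decomposition of a trajectory into tertiary-only (T) and
# quaternary-only (Q) parts relative to a reference structure.
#
# For every frame and every partition group (chain), the optimal rigid
# transform posing the reference chain onto the raw chain is computed once
# and stored. The tertiary-only frame applies the inverse pose to the raw
# chain (all chains share the reference centre-of-mass and orientation,
# leaving only subunit-internal fluctuations); the quaternary-only frame
# applies the pose to the rigid reference chain (rigid bodies posed in
# space, no internal changes). Because both parts derive from the same
# stored pose, recombination reproduces the raw frame to machine precision.
#
# The Q trajectory is expressed in full 3N Cartesian coordinates so that
# quaternary and tertiary modes live in one common vector space and scalar
# products between them are well defined.

#' Decompose a trajectory into tertiary-only and quaternary-only parts
#'
#' @param traj A `qt_trajectory` sharing the reference's atom table.
#' @param reference A `structure_frame`, typically the T-state structure.
#' @param partition Chain partition; default the reference's.
#' @param weights Optional per-atom superposition weights (e.g. masses);
#'   default unweighted.
#' @return Object of class `qt_decomposition`: list with elements
#'   `tertiary` and `quaternary` (`qt_trajectory`s), `poses` (per frame, a
#'   list of per-chain `rigid_transform`s mapping the reference chain onto
#'   the raw chain), and `reference`.
#' @export
#' @seealso [tertiary_only()], [quaternary_only()], [recombine()]
decompose_trajectory <- function(traj, reference,
                                 partition = reference$partition,
                                 weights = NULL) {
  if (n_atoms(traj) != n_atoms(reference))
    stop("trajectory and reference must share one atom table")
  .check_partition(partition, n_atoms(reference))
  if (any(lengths(partition) < 3L))
    stop("every chain needs at least 3 atoms for superposition")
  nf <- n_frames(traj)
  ref_mat <- xyz_mat(reference$xyz)
  tert <- matrix(NA_real_, nf, ncol(traj$xyz))
  quat <- matrix(NA_real_, nf, ncol(traj$xyz))
  poses <- vector("list", nf)
  for (f in seq_len(nf)) {
    raw <- xyz_mat(traj$xyz[f, ])
    tmat <- raw
    qmat <- raw
    fp <- vector("list", length(partition))
    for (ci in seq_along(partition)) {
      idx <- partition[[ci]]
      w <- if (is.null(weights)) NULL else weights[idx]
      pose <- kabsch_fit(ref_mat[idx, , drop = FALSE],
                         raw[idx, , drop = FALSE], w)
      inv <- invert_transform(pose)
      tmat[idx, ] <- apply_transform(raw[idx, , drop = FALSE], inv)
      qmat[idx, ] <- apply_transform(ref_mat[idx, , drop = FALSE], pose)
      fp[[ci]] <- pose
    }
    names(fp) <- names(partition)
    poses[[f]] <- fp
    tert[f, ] <- xyz_vec(tmat)
    quat[f, ] <- xyz_vec(qmat)
  }
  structure(list(
    tertiary = trajectory(tert, traj$atoms, partition, traj$times,
                          provenance = "tertiary_only"),
    quaternary = trajectory(quat, traj$atoms, partition, traj$times,
                            provenance = "quaternary_only"),
    poses = poses,
    reference = reference),
    class = "qt_decomposition")
}

#' @export
print.qt_decomposition <- function(x, ...) {
  cat(sprintf("qt_decomposition: %d frames, %d chains\n",
              n_frames(x$tertiary), length(x$reference$partition)))
  invisible(x)
}

#' Tertiary-only trajectory (per-chain superposition onto the reference)
#'
#' Every chain of every frame is least-squares superposed onto the
#' corresponding reference chain, removing its six rigid-body degrees of
#' freedom; for C chains this leaves 3N - 6C internal degrees of freedom.
#'
#' @inheritParams decompose_trajectory
#' @return A `qt_trajectory` with provenance `tertiary_only`.
#' @export
tertiary_only <- function(traj, reference, partition = reference$partition,
                          weights = NULL) {
  decompose_trajectory(traj, reference, partition, weights)$tertiary
}

#' Quaternary-only trajectory (rigid reference chains posed on the frames)
#'
#' Each output frame consists of rigid copies of the reference chains at
#' the least-squares pose onto the corresponding raw chains: only the six
#' rigid-body degrees of freedom per chain remain (6C - 6 after removing
#' the global fit).
#'
#' @inheritParams decompose_trajectory
#' @return A `qt_trajectory` with provenance `quaternary_only`.
#' @export
quaternary_only <- function(traj, reference, partition = reference$partition,
                            weights = NULL) {
  decompose_trajectory(traj, reference, partition, weights)$quaternary
}

#' Recombine a decomposed frame into the original structure
#'
#' Applies the stored per-chain pose to the tertiary-only coordinates,
#' reproducing the raw frame exactly (the pose was stored, not re-fitted).
#'
#' @param decomposed A `qt_decomposition`.
#' @param frame_index Frame to recombine (1-based).
#' @return A `structure_frame` equal to the original raw frame.
#' @export
recombine <- function(decomposed, frame_index) {
  nf <- n_frames(decomposed$tertiary)
  if (frame_index < 1L || frame_index > nf) stop("frame index out of range")
  tmat <- xyz_mat(decomposed$tertiary$xyz[frame_index, ])
  partition <- decomposed$tertiary$partition
  for (ci in seq_along(partition)) {
    idx <- partition[[ci]]
    tmat[idx, ] <- apply_transform(tmat[idx, , drop = FALSE],
                                   decomposed$poses[[frame_index]][[ci]])
  }
  structure_frame(tmat, decomposed$tertiary$atoms, partition,
                  provenance = "raw")
}

#' Remove the global rigid-body fit from a trajectory
#'
#' Whole-molecule least-squares fit of every frame onto the reference,
#' removing the six global degrees of freedom.
#'
#' @inheritParams decompose_trajectory
#' @return A `qt_trajectory` with the same provenance as the input.
#' @export
remove_global_fit <- function(traj, reference, weights = NULL) {
  if (n_atoms(traj) != n_atoms(reference))
    stop("trajectory and reference must share one atom table")
  ref_mat <- xyz_mat(reference$xyz)
  out <- traj$xyz
  for (f in seq_len(n_frames(traj))) {
    raw <- xyz_mat(traj$xyz[f, ])
    tf <- kabsch_fit(raw, ref_mat, weights)
    out[f, ] <- xyz_vec(apply_transform(raw, tf))
  }
  trajectory(out, traj$atoms, traj$partition, traj$times,
             provenance = traj$provenance)
}

#' Covariance spectrum and effective rank of a trajectory
#'
#' Eigen-decomposes the coordinate covariance about the trajectory mean and
#' counts eigenvalues above `tol` times the largest. For a quaternary-only
#' trajectory of C chains with the global fit removed, the count is bounded
#' by 6C - 6 (18 for a tetramer); for a tertiary-only trajectory it is
#' bounded by 3N - 6C. These are tangent-space (small-displacement) bounds:
#' finite rigid rotations curve the pose manifold, so at large amplitudes
#' curvature contributes small additional eigenvalues of relative size
#' about (amplitude / chain size)^2.
#'
#' @param traj A `qt_trajectory` (globally fitted to a common reference).
#' @param tol Relative eigenvalue threshold for the rank count.
#' @return List with `values` (variances in nm^2, descending), `rank`
#'   (count above threshold) and `tol`.
#' @export
covariance_spectrum <- function(traj, tol = 1e-12) {
  xc <- sweep(traj$xyz, 2L, colMeans(traj$xyz))
  d <- svd(xc, nu = 0L, nv = 0L)$d
  values <- d^2 / max(1L, n_frames(traj) - 1L)
  list(values = values, rank = sum(values > tol * values[1L]), tol = tol)
}

#' Pose table of a decomposition
#'
#' Flattens the stored per-frame, per-chain rigid transforms into a table
#' with unit quaternions (w, x, y, z) and translations in nm.
#'
#' @param decomposed A `qt_decomposition`.
#' @return data.frame with columns frame, chain, qw, qx, qy, qz, tx, ty, tz.
#' @export
pose_table <- function(decomposed) {
  rows <- list()
  for (f in seq_along(decomposed$poses)) {
    for (ch in names(decomposed$poses[[f]])) {
      tf <- decomposed$poses[[f]][[ch]]
      q <- .rot_to_quat(tf$rotation)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, chain = ch, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
        tx = tf$translation[1], ty = tf$translation[2],
        tz = tf$translation[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.rot_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else {
    i <- which.max(c(r[1, 1], r[2, 2], r[3, 3]))
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    s <- sqrt(max(0, r[i, i] - r[j, j] - r[k, k] + 1)) * 2
    q <- numeric(4)
    q[1] <- (r[k, j] - r[j, k]) / s
    q[i + 1L] <- 0.25 * s
    q[j + 1L] <- (r[j, i] + r[i, j]) / s
    q[k + 1L] <- (r[k, i] + r[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q
}
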