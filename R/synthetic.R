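# Synthetic multi-chain trajectory generator with planted, linearly
# coupled tertiary and quaternary motions.
#
# The generated system emulates the statistical structure assumed by the
# coupling analysis: a scalar progress variable q(t) (smooth sigmoidal
# T -> R crossing plus a small autocorrelated fluctuation) drives both a
# per-chain rigid-body path (rotation about a chain axis plus translation
# towards the assembly centre, closing the inter-chain interfaces) and a
# planted internal mode whose amplitude is alpha * q(t). Independent
# internal noise modes, per-chain rigid-body jitter and isotropic
# positional noise are superimposed. The planted internal mode is the
# rigid-free projection of the reversed interface approach, so moving
# along the quaternary path without the coupled tertiary retraction closes
# the interfaces (large van der Waals overlap) while the coupled motion
# keeps them open — the qualitative overlap landscape the analysis is
# designed to expose.

#' Specification of a synthetic coupled-motion trajectory
#'
#' Defaults define the package's reference study conditions: a 4-chain,
#' 50-beads-per-chain system over 2000 frames whose planted coupling has a
#' nominal signal-to-noise ratio alpha * sd(q) / noise_sigma of about 10.
#'
#' @param n_chains Number of chains (default 4).
#' @param atoms_per_chain Beads per chain (>= 4, default 50).
#' @param n_frames Frames to generate (default 2000).
#' @param theta_max Quaternary rotation amplitude per chain at q = 1, rad.
#' @param d_max Quaternary translation amplitude towards the centre at
#'   q = 1, nm.
#' @param coupling_alpha Amplitude (nm) of the planted internal mode per
#'   unit q; 0 removes the coupling.
#' @param n_tertiary_noise_modes Number of independent internal noise
#'   modes.
#' @param noise_mode_sd Per-frame amplitude sd of each noise mode, nm.
#' @param noise_sigma Isotropic per-coordinate positional noise sd, nm.
#' @param rigid_jitter_rot_sd Per-frame, per-chain random rigid rotation
#'   sd, rad (excites all quaternary degrees of freedom).
#' @param rigid_jitter_trans_sd Per-frame, per-chain random rigid
#'   translation sd, nm.
#' @param q_midpoint,q_width Centre and width of the sigmoidal q(t) ramp,
#'   as fractions of the trajectory length.
#' @param q_jitter_sd Sd of the AR(1) fluctuation added to q(t).
#' @param chain_separation Distance of each chain centre from the assembly
#'   centre, nm.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Object of class `qt_synth_spec` (validated parameter list).
#' @export
synthetic_spec <- function(n_chains = 4L, atoms_per_chain = 50L,
                           n_frames = 2000L, theta_max = 0.15,
                           d_max = 0.25, coupling_alpha = 0.5,
                           n_tertiary_noise_modes = 5L,
                           noise_mode_sd = 0.05, noise_sigma = 0.02,
                           rigid_jitter_rot_sd = 0.02,
                           rigid_jitter_trans_sd = 0.02,
                           q_midpoint = 0.5, q_width = 0.05,
                           q_jitter_sd = 0.05,
                           chain_separation = 0.95, seed = 1L) {
  spec <- list(n_chains = as.integer(n_chains),
               atoms_per_chain = as.integer(atoms_per_chain),
               n_frames = as.integer(n_frames), theta_max = theta_max,
               d_max = d_max, coupling_alpha = coupling_alpha,
               n_tertiary_noise_modes = as.integer(n_tertiary_noise_modes),
               noise_mode_sd = noise_mode_sd, noise_sigma = noise_sigma,
               rigid_jitter_rot_sd = rigid_jitter_rot_sd,
               rigid_jitter_trans_sd = rigid_jitter_trans_sd,
               q_midpoint = q_midpoint, q_width = q_width,
               q_jitter_sd = q_jitter_sd,
               chain_separation = chain_separation, seed = as.integer(seed))
  stopifnot(spec$n_chains >= 2L, spec$atoms_per_chain >= 4L,
            spec$n_frames >= 1L)
  num <- unlist(spec[c("theta_max", "d_max", "coupling_alpha",
                       "noise_mode_sd", "noise_sigma",
                       "rigid_jitter_rot_sd", "rigid_jitter_trans_sd",
                       "q_jitter_sd", "chain_separation")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("amplitudes must be finite and nonnegative")
  structure(spec, class = "qt_synth_spec")
}

#' @export
print.qt_synth_spec <- function(x, ...) {
  cat(sprintf(paste0("qt_synth_spec: %d chains x %d beads, %d frames, ",
                     "alpha = %g, sigma = %g, seed = %d\n"),
              x$n_chains, x$atoms_per_chain, x$n_frames, x$coupling_alpha,
              x$noise_sigma, x$seed))
  invisible(x)
}

# Rodrigues rotation matrix from a rotation vector.
.rotvec_to_mat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  a <- w / th
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Per-chain geometry helpers shared by reference and truth construction.
.synth_layout <- function(spec) {
  phi <- 2 * pi * (seq_len(spec$n_chains) - 1L) / spec$n_chains + pi / 4
  centers <- cbind(spec$chain_separation * cos(phi),
                   spec$chain_separation * sin(phi), 0)
  dirs <- -centers / sqrt(rowSums(centers^2))       # towards the centre
  axes <- matrix(rep(c(0, 0, 1), spec$n_chains), ncol = 3, byrow = TRUE)
  list(centers = centers, dirs = dirs, axes = axes)
}

#' Reference structure of the synthetic system
#'
#' Chains are helical bead strands (non-collinear by construction) placed
#' symmetrically around the assembly centre with facing interfaces that
#' the quaternary path can close. Deterministic: no random draws.
#'
#' @param spec A `qt_synth_spec`.
#' @return A `structure_frame` with provenance `synthetic`.
#' @export
make_reference <- function(spec) {
  lay <- .synth_layout(spec)
  n <- spec$atoms_per_chain
  t_ <- seq_len(n)
  local <- cbind(0.35 * cos(0.55 * t_), 0.35 * sin(0.55 * t_),
                 2.0 * (t_ - (n + 1) / 2) / n)
  coords <- NULL
  for (c_ in seq_len(spec$n_chains)) {
    # rotate each chain's helix phase so the interfaces are not identical
    rot <- .rotvec_to_mat(c(0, 0, 2 * pi * (c_ - 1) / spec$n_chains))
    coords <- rbind(coords, sweep(local %*% t(rot), 2L,
                                  lay$centers[c_, ], "+"))
  }
  atoms <- atom_table(element = "C",
                      chain = rep(LETTERS[seq_len(spec$n_chains)], each = n),
                      resno = rep(t_, spec$n_chains), resid = "BEA",
                      name = "C")
  structure_frame(coords, atoms, provenance = "synthetic")
}

# Linearised quaternary displacement field (3N) of the coherent rigid path
# at the reference, and the planted internal (tertiary) mode derived from
# the reversed interface approach.
.synth_truth_dirs <- function(spec, ref) {
  lay <- .synth_layout(spec)
  mat <- xyz_mat(ref$xyz)
  n3 <- length(ref$xyz)
  uq <- numeric(n3)
  for (c_ in seq_len(spec$n_chains)) {
    idx <- ref$partition[[c_]]
    rel <- sweep(mat[idx, , drop = FALSE], 2L, lay$centers[c_, ])
    rot <- t(apply(rel, 1L, function(p) .cross3(lay$axes[c_, ], p)))
    field <- spec$theta_max * rot +
      matrix(spec$d_max * lay$dirs[c_, ], nrow = length(idx), ncol = 3,
             byrow = TRUE)
    rows <- as.vector(t(outer(idx, 1:3, function(i, k) 3L * (i - 1L) + k)))
    uq[rows] <- as.vector(t(field))
  }
  nq <- sqrt(sum(uq^2))
  uq_unit <- if (nq > 0) uq / nq else uq
  # interface beads: per chain, the quarter of beads nearest the centre
  mask <- numeric(n3)
  for (c_ in seq_len(spec$n_chains)) {
    idx <- ref$partition[[c_]]
    dist0 <- sqrt(rowSums(mat[idx, , drop = FALSE]^2))
    m <- max(2L, ceiling(length(idx) / 4))
    pick <- idx[order(dist0)[seq_len(m)]]
    rows <- as.vector(t(outer(pick, 1:3, function(i, k) 3L * (i - 1L) + k)))
    mask[rows] <- 1
  }
  mt_raw <- as.numeric(.project_internal(-uq * mask, ref))
  nmt <- sqrt(sum(mt_raw^2))
  mt <- if (nmt > 0) mt_raw / nmt else .fallback_internal(ref)
  list(uq = uq_unit, mt = mt)
}

.fallback_internal <- function(ref) {
  v <- sin(seq_along(ref$xyz))
  v <- as.numeric(.project_internal(v, ref))
  v / sqrt(sum(v^2))
}

# Build one conformation at given q with given internal displacement and
# rigid jitter (zero jitter for the deterministic end states).
.synth_frame <- function(spec, ref, lay, q, internal_disp, rot_jit,
                         trans_jit) {
  y <- xyz_mat(ref$xyz + internal_disp)
  for (c_ in seq_len(spec$n_chains)) {
    idx <- ref$partition[[c_]]
    w <- lay$axes[c_, ] * spec$theta_max * q + rot_jit[c_, ]
    r <- .rotvec_to_mat(w)
    tr <- spec$d_max * q * lay$dirs[c_, ] + trans_jit[c_, ]
    cen <- lay$centers[c_, ]
    y[idx, ] <- sweep(sweep(y[idx, , drop = FALSE], 2L, cen) %*% t(r),
                      2L, cen + tr, "+")
  }
  xyz_vec(y)
}

#' Generate a synthetic coupled-motion trajectory
#'
#' Each frame is built as rigid_pose(q(t)) applied per chain to
#' reference + alpha * q(t) * tertiary_mode + sum_k b_k(t) * noise_mode_k
#' + isotropic noise, with the noise-mode amplitudes b_k independent of q.
#'
#' @param spec A `qt_synth_spec`.
#' @return List with `trajectory` (a `qt_trajectory`, provenance
#'   `synthetic`), `truth` (planted ground truth: `q_series`,
#'   `quaternary_mode_direction`, `tertiary_mode_direction`,
#'   `noise_mode_directions`, all unit 3N-vectors with zero per-chain
#'   rigid content for the internal ones) and `reference`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "qt_synth_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  ref <- make_reference(spec)
  lay <- .synth_layout(spec)
  dirs <- .synth_truth_dirs(spec, ref)
  n3 <- length(ref$xyz)
  nf <- spec$n_frames
  # progress variable: sigmoid ramp + AR(1) fluctuation
  tt <- seq_len(nf)
  q <- stats::plogis((tt - spec$q_midpoint * nf) /
                       max(spec$q_width * nf, 1e-9))
  if (spec$q_jitter_sd > 0 && nf > 1L) {
    eps <- stats::rnorm(nf, 0, spec$q_jitter_sd * sqrt(1 - 0.9^2))
    jit <- Reduce(function(a, b) 0.9 * a + b, eps, accumulate = TRUE)
    q <- q + jit
  }
  # internal noise modes: rigid-free, orthogonal to the planted mode
  K <- spec$n_tertiary_noise_modes
  noise_modes <- NULL
  if (K > 0L) {
    noise_modes <- matrix(0, n3, K)
    basis <- cbind(dirs$mt)
    for (k in seq_len(K)) {
      v <- as.numeric(.project_internal(stats::rnorm(n3), ref))
      v <- v - basis %*% crossprod(basis, v)
      v <- as.numeric(v) / sqrt(sum(v^2))
      noise_modes[, k] <- v
      basis <- cbind(basis, v)
    }
  }
  b <- if (K > 0L) matrix(stats::rnorm(nf * K, 0, spec$noise_mode_sd),
                          nf, K) else NULL
  rot_jit <- array(stats::rnorm(nf * spec$n_chains * 3, 0,
                                spec$rigid_jitter_rot_sd),
                   dim = c(spec$n_chains, 3, nf))
  trans_jit <- array(stats::rnorm(nf * spec$n_chains * 3, 0,
                                  spec$rigid_jitter_trans_sd),
                     dim = c(spec$n_chains, 3, nf))
  iso <- if (spec$noise_sigma > 0)
    matrix(stats::rnorm(nf * n3, 0, spec$noise_sigma), nf, n3) else NULL
  xyz <- matrix(NA_real_, nf, n3)
  for (f in seq_len(nf)) {
    disp <- spec$coupling_alpha * q[f] * dirs$mt
    if (K > 0L) disp <- disp + as.numeric(noise_modes %*% b[f, ])
    if (!is.null(iso)) disp <- disp + iso[f, ]
    xyz[f, ] <- .synth_frame(spec, ref, lay, q[f], disp,
                             rot_jit[, , f], trans_jit[, , f])
  }
  traj <- trajectory(xyz, ref$atoms, ref$partition, provenance = "synthetic")
  truth <- list(q_series = q, quaternary_mode_direction = dirs$uq,
                tertiary_mode_direction = dirs$mt,
                noise_mode_directions = noise_modes)
  list(trajectory = traj, truth = truth, reference = ref)
}

#' Noise-free end states (T and R) of the synthetic system
#'
#' The conformations at q = 0 and q = 1 with all noise, jitter and
#' fluctuation terms switched off; used as synthetic stand-ins for the
#' crystallographic end states in transition detection and difference-mode
#' analyses.
#'
#' @param spec A `qt_synth_spec`.
#' @return List with `t_state` and `r_state` (`structure_frame`s).
#' @export
synthetic_endpoints <- function(spec) {
  ref <- make_reference(spec)
  lay <- .synth_layout(spec)
  dirs <- .synth_truth_dirs(spec, ref)
  zero <- matrix(0, spec$n_chains, 3)
  mk <- function(q) structure_frame(
    xyz_mat(.synth_frame(spec, ref, lay, q,
                         spec$coupling_alpha * q * dirs$mt, zero, zero)),
    ref$atoms, ref$partition, provenance = "synthetic")
  list(t_state = mk(0), r_state = mk(1))
}

#' Concatenate trajectories over a shared atom table
#'
#' Frames are appended in the given order (the standard preparation for a
#' split-half functional mode analysis over several transition runs).
#'
#' @param trajs List of `qt_trajectory`s with identical atom tables.
#' @return A single `qt_trajectory`.
#' @export
concat_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  n <- vapply(trajs, n_atoms, integer(1))
  if (length(unique(n)) != 1L) stop("atom tables differ in size")
  trajectory(do.call(rbind, lapply(trajs, function(tr) tr$xyz)),
             trajs[[1L]]$atoms, trajs[[1L]]$partition,
             provenance = trajs[[1L]]$provenance)
}
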