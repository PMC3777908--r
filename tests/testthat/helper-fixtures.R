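# Shared fixtures, built in code.

# Random non-degenerate point cloud.
rand_cloud <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n), ncol = 3)
}

# Rotation matrix about an axis by an angle (Rodrigues).
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# Two-chain frame with hand-set radii; chains of `n_per` atoms each.
two_chain_frame <- function(coords, n_per = nrow(coords) / 2,
                            radius = 0.15) {
  atoms <- atom_table(element = "C",
                      chain = rep(c("A", "B"), each = n_per),
                      resno = rep(seq_len(n_per), 2),
                      radius = radius)
  structure_frame(coords, atoms)
}

# Column-centred matrix with exactly orthonormal columns spans
# (X^T X = I, zero column means): an exactly isotropic predictor block.
whitened_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  z <- sweep(z, 2L, colMeans(z))
  sv <- svd(z)
  sv$u %*% t(sv$v)
}

# Small fast synthetic system for unit tests.
small_spec <- function(seed = 1, n_frames = 60, ...) {
  synthetic_spec(atoms_per_chain = 20L, n_frames = n_frames, seed = seed,
                 ...)
}

# The split-half FMA protocol on two concatenated synthetic runs:
# decompose, PCA of the fitted quaternary part, PLS-FMA of the tertiary
# part against the cQ projection, component count chosen by
# cross-validation and the final model refit on all frames.
fma_protocol <- function(seed, n_frames_each = 1000L, k_max = 10L,
                         alpha = 0.5, atoms_per_chain = 50L) {
  runs <- lapply(seed * 1000L + c(1L, 2L), function(s)
    generate_trajectory(synthetic_spec(
      atoms_per_chain = atoms_per_chain, n_frames = n_frames_each,
      coupling_alpha = alpha, seed = s)))
  traj <- concat_trajectories(lapply(runs, `[[`, "trajectory"))
  ref <- runs[[1L]]$reference
  dec <- decompose_trajectory(traj, ref)
  qf <- remove_global_fit(dec$quaternary, ref)
  cQ <- pca_mode(traj_pca(qf))
  sel <- select_components(dec$tertiary, project_mode(qf, cQ), k_max)
  list(model = sel$split_model, final = sel$model, k_best = sel$k_best,
       truth = runs[[1L]]$truth, decomposition = dec, cQ = cQ,
       reference = ref)
}

# Independent brute-force vdW overlap oracle: double loop over all pairs.
oracle_overlap <- function(frame) {
  mat <- xyz_mat(frame$xyz)
  at <- frame$atoms
  chain <- integer(nrow(mat))
  for (ci in seq_along(frame$partition))
    chain[frame$partition[[ci]]] <- ci
  total <- 0
  for (i in seq_len(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      if (chain[i] == chain[j]) next
      d <- sqrt(sum((mat[i, ] - mat[j, ])^2))
      total <- total + max(0, at$radius[i] + at$radius[j] - d)
    }
  }
  total
}

# Minimal multi-residue PDB text (protein + heme-like HETATM + water +
# ion + hydrogens) for reader/selection tests.
write_mini_pdb <- function(file) {
  fmt <- function(type, i, name, resid, chain, resno, x, y, z, ele)
    sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, i, name, resid, chain, resno, x, y, z, 1, 0, ele)
  lines <- c(
    fmt("ATOM", 1, "N",   "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    fmt("ATOM", 2, "CA",  "ALA", "A", 1, 1.5, 0.0, 0.0, "C"),
    fmt("ATOM", 3, "C",   "ALA", "A", 1, 2.1, 1.4, 0.0, "C"),
    fmt("ATOM", 4, "O",   "ALA", "A", 1, 1.5, 2.4, 0.0, "O"),
    fmt("ATOM", 5, "HA",  "ALA", "A", 1, 1.8, -0.9, 0.3, "H"),
    fmt("ATOM", 6, "N",   "GLY", "B", 2, 0.0, 0.0, 3.0, "N"),
    fmt("ATOM", 7, "CA",  "GLY", "B", 2, 1.5, 0.0, 3.0, "C"),
    fmt("ATOM", 8, "C",   "GLY", "B", 2, 2.1, 1.4, 3.0, "C"),
    fmt("ATOM", 9, "H",   "GLY", "B", 2, -0.5, -0.8, 3.0, "H"),
    fmt("HETATM", 10, "FE", "HEM", "B", 90, 5.0, 5.0, 5.0, "FE"),
    fmt("HETATM", 11, "C1", "HEM", "B", 90, 6.2, 5.0, 5.0, "C"),
    fmt("HETATM", 12, "O",  "HOH", "B", 101, 9.0, 9.0, 9.0, "O"),
    fmt("HETATM", 13, "CL", "CL",  "B", 102, 11.0, 9.0, 9.0, "CL"),
    "END")
  writeLines(lines, file)
  file
}
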