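test_that("reference-only input is a fixed point of the decomposition", {
  spec <- small_spec()
  ref <- make_reference(spec)
  traj <- trajectory(rbind(ref$xyz, ref$xyz, ref$xyz), ref$atoms,
                     ref$partition)
  dec <- decompose_trajectory(traj, ref)
  expect_lt(max(abs(dec$tertiary$xyz - rep(ref$xyz, each = 3))), 1e-10)
  expect_lt(max(abs(dec$quaternary$xyz - rep(ref$xyz, each = 3))), 1e-10)
  expect_lt(max(abs(recombine(dec, 2)$xyz - ref$xyz)), 1e-10)
})

test_that("pure per-chain rigid motion is removed by tertiary_only and
           recovered as poses by quaternary_only", {
  spec <- small_spec()
  ref <- make_reference(spec)
  planted <- list(
    A = rigid_transform(rot_about(c(0, 0, 1), 0.3), c(0.1, 0, 0)),
    B = rigid_transform(rot_about(c(1, 1, 0), -0.2), c(0, -0.2, 0.1)),
    C = rigid_transform(diag(3), c(0.3, 0.3, 0)),
    D = rigid_transform(rot_about(c(0, 1, 0), 0.15), c(0, 0, 0)))
  xyz <- ref$xyz
  for (ch in names(planted))
    xyz <- apply_transform(xyz, planted[[ch]], ref$partition[[ch]])
  traj <- trajectory(matrix(xyz, nrow = 1), ref$atoms, ref$partition)
  dec <- decompose_trajectory(traj, ref)
  # rigid motion removed exactly from the tertiary part
  expect_lt(max(abs(dec$tertiary$xyz[1, ] - ref$xyz)), 1e-9)
  # poses equal the planted transforms
  for (ch in names(planted)) {
    expect_lt(max(abs(dec$poses[[1]][[ch]]$rotation -
                        planted[[ch]]$rotation)), 1e-8)
    expect_lt(max(abs(dec$poses[[1]][[ch]]$translation -
                        planted[[ch]]$translation)), 1e-8)
  }
  # quaternary frame equals the planted frame (reference is rigid here)
  expect_lt(max(abs(dec$quaternary$xyz[1, ] - xyz)), 1e-9)
})

test_that("recombination reproduces raw frames exactly for mixed motion", {
  g <- generate_trajectory(small_spec(seed = 21, n_frames = 25))
  dec <- decompose_trajectory(g$trajectory, g$reference)
  for (i in seq_len(25)) {
    expect_lt(max(abs(recombine(dec, i)$xyz - g$trajectory$xyz[i, ])),
              1e-9)
  }
  expect_error(recombine(dec, 26), "out of range")
})

test_that("tertiary frames are orthogonal to every chain rigid-body vector", {
  # linear-order property: amplitudes small enough that the quadratic
  # leakage of the per-chain fit stays below the asserted bound
  spec <- small_spec(seed = 31, n_frames = 20,
                     coupling_alpha = 1e-7, noise_mode_sd = 1e-7,
                     noise_sigma = 1e-7, rigid_jitter_rot_sd = 1e-7,
                     rigid_jitter_trans_sd = 1e-7)
  g <- generate_trajectory(spec)
  dec <- decompose_trajectory(g$trajectory, g$reference)
  b <- rigid_basis(g$reference)
  disp <- sweep(dec$tertiary$xyz, 2L, g$reference$xyz)
  ip <- abs(disp %*% b)           # frames x 24 rigid components
  norms <- sqrt(rowSums(disp^2))
  expect_lt(max(ip / norms), 1e-6)
})

test_that("covariance rank bounds hold in the small-displacement regime", {
  # quaternary-only: exactly 6C - 6 = 18 dimensions for 4 chains
  spec <- synthetic_spec(atoms_per_chain = 20L, n_frames = 400L,
                         theta_max = 0, d_max = 0, coupling_alpha = 0,
                         n_tertiary_noise_modes = 0L, noise_mode_sd = 0,
                         noise_sigma = 0, rigid_jitter_rot_sd = 1e-7,
                         rigid_jitter_trans_sd = 1e-7, q_jitter_sd = 0,
                         seed = 41)
  g <- generate_trajectory(spec)
  dec <- decompose_trajectory(g$trajectory, g$reference)
  qf <- remove_global_fit(dec$quaternary, g$reference)
  expect_identical(covariance_spectrum(qf)$rank, 18L)
  # tertiary-only: at most 3N - 24 dimensions
  spec_t <- synthetic_spec(atoms_per_chain = 20L, n_frames = 400L,
                           theta_max = 0, d_max = 0, coupling_alpha = 0,
                           n_tertiary_noise_modes = 0L, noise_mode_sd = 0,
                           noise_sigma = 1e-7, rigid_jitter_rot_sd = 0,
                           rigid_jitter_trans_sd = 0, q_jitter_sd = 0,
                           seed = 42)
  gt <- generate_trajectory(spec_t)
  tert <- tertiary_only(gt$trajectory, gt$reference)
  n3 <- 3L * n_atoms(gt$reference)
  expect_lte(covariance_spectrum(tert)$rank, n3 - 24L)
})

test_that("remove_global_fit is idempotent and maps rotated copies back", {
  spec <- small_spec()
  ref <- make_reference(spec)
  tf <- rigid_transform(rot_about(c(1, 0, 0), 1.1), c(2, 0, -1))
  rot <- apply_transform(ref$xyz, tf)
  traj <- trajectory(matrix(rot, nrow = 1), ref$atoms, ref$partition)
  fit1 <- remove_global_fit(traj, ref)
  expect_lt(max(abs(fit1$xyz[1, ] - ref$xyz)), 1e-9)
  fit2 <- remove_global_fit(fit1, ref)
  expect_lt(max(abs(fit2$xyz - fit1$xyz)), 1e-10)
  # fitted RMSD never exceeds unfitted
  g <- generate_trajectory(small_spec(seed = 51, n_frames = 10))
  fitg <- remove_global_fit(g$trajectory, g$reference)
  for (i in 1:10) {
    expect_lte(coord_rmsd(fitg$xyz[i, ], g$reference$xyz),
               coord_rmsd(g$trajectory$xyz[i, ], g$reference$xyz) + 1e-12)
  }
})

test_that("pose_table flattens poses to quaternions that rebuild rotations", {
  g <- generate_trajectory(small_spec(seed = 61, n_frames = 3))
  dec <- decompose_trajectory(g$trajectory, g$reference)
  pt <- pose_table(dec)
  expect_identical(nrow(pt), 3L * 4L)
  expect_identical(names(pt),
                   c("frame", "chain", "qw", "qx", "qy", "qz",
                     "tx", "ty", "tz"))
  # unit quaternions
  expect_equal(pt$qw^2 + pt$qx^2 + pt$qy^2 + pt$qz^2, rep(1, nrow(pt)),
               tolerance = 1e-10)
  # quaternion of frame 2 chain B rebuilds its rotation matrix
  row <- pt[pt$frame == 2 & pt$chain == "B", ]
  q <- as.numeric(row[c("qw", "qx", "qy", "qz")])
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  expect_lt(max(abs(r - dec$poses[[2]][["B"]]$rotation)), 1e-8)
})
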