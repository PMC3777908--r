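test_that("vdw_overlap computes per-pair penetration depths", {
  # two atoms in different chains, r = 0.15 nm each, d = 0.20 nm -> 0.10
  fr <- two_chain_frame(rbind(c(0, 0, 0), c(0.2, 0, 0)), n_per = 1)
  ov <- vdw_overlap(fr)
  expect_equal(ov$total, 0.10, tolerance = 1e-12)
  # per-atom accounting attributes the pair to both atoms
  ov2 <- vdw_overlap(fr, per_atom = TRUE, double_count = TRUE)
  expect_equal(ov2$total, 0.20, tolerance = 1e-12)
  expect_equal(ov2$per_atom, c(0.10, 0.10), tolerance = 1e-12)
  # separated atoms: exactly zero
  fr0 <- two_chain_frame(rbind(c(0, 0, 0), c(0.5, 0, 0)), n_per = 1)
  expect_identical(vdw_overlap(fr0)$total, 0)
  # intra-chain pairs never counted
  fr3 <- two_chain_frame(rbind(c(0, 0, 0), c(0.1, 0, 0),
                               c(5, 0, 0), c(5.1, 0, 0)), n_per = 2)
  expect_identical(vdw_overlap(fr3)$total, 0)
  # missing radius names the atom
  frb <- two_chain_frame(rbind(c(0, 0, 0), c(0.2, 0, 0)), n_per = 1)
  frb$atoms$radius[2] <- NA
  expect_error(vdw_overlap(frb), "atom")
})

test_that("vdw_overlap is invariant under rigid motion and monotone in
           pair distance", {
  set.seed(5)
  # chain A in x < 0, chain B in x > 0: shifting B along +x increases
  # every inter-chain distance
  coords <- rbind(cbind(runif(10, -0.4, -0.05), runif(10), runif(10)),
                  cbind(runif(10, 0.05, 0.4), runif(10), runif(10)))
  fr <- two_chain_frame(coords)
  t0 <- vdw_overlap(fr)$total
  expect_gt(t0, 0)
  tf <- rigid_transform(rot_about(c(1, 2, 0), 0.9), c(3, -1, 2))
  fr_rot <- structure_frame(apply_transform(fr$xyz, tf), fr$atoms)
  expect_equal(vdw_overlap(fr_rot)$total, t0, tolerance = 1e-10)
  # increasing all inter-chain distances can only decrease the total
  for (shift in c(0.05, 0.1, 0.2, 0.5)) {
    co2 <- coords
    co2[11:20, 1] <- co2[11:20, 1] + shift
    tot <- vdw_overlap(two_chain_frame(co2))$total
    expect_lte(tot, t0 + 1e-12)
    t0 <- tot
  }
  # pairwise monotonicity: penetration is non-increasing in distance
  pen <- vapply(seq(0.1, 0.4, by = 0.05), function(d)
    vdw_overlap(two_chain_frame(rbind(c(0, 0, 0), c(d, 0, 0)),
                                n_per = 1))$total, numeric(1))
  expect_true(all(diff(pen) <= 1e-12))
})

test_that("accelerated pair search equals brute force exactly on
           500-atom frames", {
  set.seed(11)
  coords <- matrix(runif(500 * 3, 0, 2.5), ncol = 3)
  atoms <- atom_table(element = "C",
                      chain = rep(c("A", "B", "C", "D"), length.out = 500),
                      resno = rep(1:125, each = 4), radius = 0.15)
  fr <- structure_frame(coords, atoms)
  pc <- interchain_pairs(fr, cutoff = 0.3, method = "cells")
  pb <- interchain_pairs(fr, cutoff = 0.3, method = "brute")
  expect_identical(pc$i, pb$i)
  expect_identical(pc$j, pb$j)
  expect_equal(pc$d, pb$d, tolerance = 1e-12)
  # per-pair overlap equals the independent double-loop oracle
  ovc <- vdw_overlap(fr, method = "cells")$total
  ovb <- vdw_overlap(fr, method = "brute")$total
  expect_equal(ovc, ovb, tolerance = 1e-12)
  expect_equal(ovc, oracle_overlap(fr), tolerance = 1e-12)
  # contact sets identical too
  cc <- find_contacts(fr, cutoff = 0.3, method = "cells")
  cb <- find_contacts(fr, cutoff = 0.3, method = "brute")
  expect_identical(cc$res_a, cb$res_a)
  expect_identical(cc$res_b, cb$res_b)
  expect_equal(cc$min_dist, cb$min_dist, tolerance = 1e-12)
})

test_that("find_contacts applies the 0.3 nm heavy-atom cutoff", {
  mk <- function(d) two_chain_frame(rbind(c(0, 0, 0), c(d, 0, 0)),
                                    n_per = 1)
  expect_identical(nrow(find_contacts(mk(0.25))), 1L)
  expect_identical(nrow(find_contacts(mk(0.35))), 0L)
  expect_identical(nrow(find_contacts(mk(0.35), cutoff = 0.4)), 1L)
  # hydrogens are ignored
  atoms <- atom_table(element = c("C", "H"), chain = c("A", "B"),
                      resno = c(1, 2))
  frh <- structure_frame(rbind(c(0, 0, 0), c(0.1, 0, 0)), atoms)
  expect_identical(nrow(find_contacts(frh)), 0L)
  # invariant under whole-frame rigid motion
  fr <- mk(0.25)
  tf <- rigid_transform(rot_about(c(0, 1, 1), 2.2), c(-4, 2, 0))
  fr2 <- structure_frame(apply_transform(fr$xyz, tf), fr$atoms)
  expect_identical(nrow(find_contacts(fr2)), 1L)
})

test_that("overlap_surface maps the grid and exposes the off-diagonal
           clash signature of planted coupling", {
  # clash-free grid: all zeros, grid-shaped
  fx_atoms <- atom_table(element = "C", chain = rep(c("A", "B"), each = 3),
                         resno = rep(1:3, 2))
  far <- structure_frame(rbind(rand_cloud(3, 1), rand_cloud(3, 2) + 10),
                         fx_atoms)
  structs <- rep(list(far), 6)
  attr(structs, "dim_grid") <- c(3L, 2L)
  surf0 <- overlap_surface(structs)
  expect_identical(dim(surf0), c(3L, 2L))
  expect_true(all(surf0 == 0))
  # planted-coupling system whose interfaces close decisively along the
  # quaternary path: moving along cQ without the coupled tertiary
  # retraction clashes, so off-diagonal overlap exceeds the diagonal
  mk <- function(s) generate_trajectory(synthetic_spec(
    atoms_per_chain = 30L, n_frames = 300L, d_max = 0.35, seed = s))
  runs <- lapply(c(29001, 29002), mk)
  traj <- concat_trajectories(lapply(runs, `[[`, "trajectory"))
  ref <- runs[[1]]$reference
  dec <- decompose_trajectory(traj, ref)
  qf <- remove_global_fit(dec$quaternary, ref)
  cQ <- pca_mode(traj_pca(qf))
  sel <- select_components(dec$tertiary, project_mode(qf, cQ), 10)
  cTew <- ensemble_weight(sel$model)
  rawfit <- remove_global_fit(runs[[1]]$trajectory, ref)
  pl <- project_plane(rawfit, cQ, cTew, ref)
  surf <- overlap_surface(build_grid(pl, 16))
  expect_identical(dim(surf), c(16L, 16L))
  diag_max <- max(diag(surf))
  n_bigger <- sum(surf[row(surf) != col(surf)] > diag_max)
  expect_gte(n_bigger, 10)
})

test_that("contact_profile assembles presence vectors along a path", {
  mk <- function(d) two_chain_frame(rbind(c(0, 0, 0), c(d, 0, 0)),
                                    n_per = 1)
  ds <- c(0.25, 0.25, 0.4, 0.4, 0.4, 0.25, 0.25)
  path <- structure(list(structures = lapply(ds, mk), corner = 4L),
                    class = "qt_path")
  cp <- contact_profile(path)
  expect_identical(nrow(cp$pairs), 1L)
  expect_identical(unname(cp$presence[1, ]),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(ncol(cp$presence), 7L)
  # a pair never within cutoff is not reported
  path_far <- structure(list(structures = lapply(rep(1, 3), mk),
                             corner = 2L), class = "qt_path")
  expect_identical(nrow(contact_profile(path_far)$pairs), 0L)
})

make_contacts <- function(pairs, presence, corner) {
  structure(list(pairs = pairs, presence = presence,
                 path_length = ncol(presence), corner = corner),
            class = "qt_contacts")
}

test_that("classify_contacts implements the pulling/pushing/switching
           scheme", {
  pairs <- data.frame(
    res_a = c("A/1/BEA", "A/2/BEA", "A/3/BEA", "A/3/BEA", "A/4/BEA"),
    res_b = c("B/1/BEA", "B/2/BEA", "B/5/BEA", "B/6/BEA", "B/7/BEA"),
    stringsAsFactors = FALSE)
  presence <- rbind(
    c(1, 1, 0, 0, 0, 1, 1),   # pulling: ends only
    c(0, 0, 1, 1, 1, 0, 0),   # pushing: elbow only
    c(1, 1, 0, 0, 0, 0, 0),   # switching: partner B/5 at the T-end ...
    c(0, 0, 0, 0, 0, 1, 1),   # ... replaced by B/6 at the R-end
    c(1, 1, 1, 1, 1, 1, 1)) == 1  # static
  cl <- classify_contacts(make_contacts(pairs, presence, corner = 4L))
  expect_identical(cl$pairs$class,
                   c("pulling", "pushing", "switching", "switching",
                     "static"))
  # classification is invariant under path reversal (T/R swap)
  rev_cl <- classify_contacts(make_contacts(
    pairs, presence[, 7:1], corner = 4L))
  expect_identical(rev_cl$pairs$class, cl$pairs$class)
  # too-short path errors
  expect_error(classify_contacts(make_contacts(
    pairs[1, ], presence[1, 1:2, drop = FALSE], corner = 1L)),
    "too short")
})
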