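test_that("traj_pca matches the eigenstructure of the sample covariance", {
  set.seed(1)
  atoms <- atom_table(element = "C", chain = rep(c("A", "B"), each = 3),
                      resno = rep(1:3, 2))
  xyz <- matrix(rnorm(40 * 18), 40, 18)
  traj <- trajectory(xyz, atoms)
  p <- traj_pca(traj)
  # trace conservation: eigenvalue sum equals total coordinate variance
  expect_equal(sum(p$values), sum(apply(xyz, 2, var)), tolerance = 1e-9)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$values) <= 1e-12))
  # orthonormal eigenvectors
  k <- ncol(p$vectors)
  expect_lt(max(abs(crossprod(p$vectors) - diag(k))), 1e-8)
  # independent oracle: stats::prcomp
  pr <- prcomp(xyz, center = TRUE, scale. = FALSE)
  expect_equal(p$values[1:10], unname(pr$sdev[1:10]^2), tolerance = 1e-9)
  for (i in 1:3)
    expect_equal(abs(sum(p$vectors[, i] * pr$rotation[, i])), 1,
                 tolerance = 1e-8)
  # two distinct frames give exactly one nonzero eigenvalue
  p2 <- traj_pca(trajectory(xyz[1:2, ], atoms))
  expect_identical(sum(p2$values > 1e-12 * p2$values[1]), 1L)
  expect_error(traj_pca(trajectory(xyz[1, , drop = FALSE], atoms)),
               "at least 2")
})

test_that("pca recovers a planted dominant quaternary mode", {
  g <- generate_trajectory(synthetic_spec(atoms_per_chain = 30L,
                                          n_frames = 500L, seed = 77))
  dec <- decompose_trajectory(g$trajectory, g$reference)
  qf <- remove_global_fit(dec$quaternary, g$reference)
  p <- traj_pca(qf)
  cQ <- pca_mode(p)
  expect_identical(cQ$role, "cQ")
  expect_gte(abs(sum(cQ$vector * g$truth$quaternary_mode_direction)), 0.99)
})

test_that("project_mode is linear and anchored at the mode origin", {
  g <- generate_trajectory(small_spec(n_frames = 5))
  ref <- g$reference
  v <- rnorm(length(ref$xyz))
  mode <- collective_mode(v, origin = ref$xyz)
  expect_equal(project_mode(ref, mode), 0, tolerance = 1e-12)
  shifted <- structure_frame(ref$xyz + 0.5 * mode$vector, ref$atoms,
                             ref$partition)
  expect_equal(project_mode(shifted, mode), 0.5, tolerance = 1e-12)
  # linearity across frames
  a <- g$trajectory$xyz[1:3, ]
  b <- g$trajectory$xyz[3:5, ]
  expect_equal(project_mode((a + b) / 2, mode),
               (project_mode(a, mode) + project_mode(b, mode)) / 2,
               tolerance = 1e-12)
  expect_error(project_mode(a[, 1:12], mode), "dimension mismatch")
})

test_that("pearson_r validates input and reproduces exact correlations", {
  expect_equal(pearson_r(1:10, 1:10), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  expect_error(pearson_r(1:3, 1:4), "lengths differ")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})

test_that("mode_overlap is the symmetric absolute scalar product", {
  m1 <- collective_mode(c(1, 0, 0, 0, 0, 0))
  m2 <- collective_mode(c(0, 1, 0, 0, 0, 0))
  expect_equal(mode_overlap(m1, m1), 1.0)
  expect_equal(mode_overlap(m1, m2), 0.0)
  m3 <- collective_mode(rnorm(6))
  expect_equal(mode_overlap(m1, m3), mode_overlap(m3, m1))
  tab <- overlap_table(list(a = m1, b = m2, c = m3))
  expect_equal(unname(diag(tab)), rep(1, 3), tolerance = 1e-12)
  expect_true(isSymmetric(tab))
})

test_that("pls_fma achieves an exact fit on an exactly linear target", {
  x <- whitened_matrix(200, 40, seed = 13)
  v <- rnorm(40)
  v <- v / sqrt(sum(v^2))
  y <- as.numeric(x %*% v)
  m <- pls_fma(x, y, n_components = 1, split = NULL)
  expect_equal(m$fit_r, 1.0, tolerance = 1e-9)
  expect_gte(abs(sum(m$mode_cT$vector * v)), 0.999)
  expect_error(pls_fma(x, rep(1, 200), 1), "zero variance")
})

test_that("pls_fma does not hallucinate coupling from a permuted target", {
  set.seed(23)
  x <- matrix(rnorm(2000 * 120), 2000, 120)
  base <- as.numeric(x %*% rnorm(120))
  cvs <- vapply(1:20, function(i) {
    pls_fma(x, sample(base), n_components = 10)$cv_r
  }, numeric(1))
  expect_lt(max(abs(cvs)), 0.2)
  expect_lt(abs(median(cvs)), 0.1)
})

test_that("pls_fma recovers a planted coupled tertiary mode from
           decomposed synthetic data", {
  res <- fma_protocol(seed = 3, n_frames_each = 400L,
                      atoms_per_chain = 30L)
  expect_gte(res$model$cv_r, 0.9)
  expect_gte(abs(sum(res$final$mode_cT$vector *
                       res$truth$tertiary_mode_direction)), 0.95)
  # the coupling mode lives in the tertiary subspace: no rigid content
  b <- rigid_basis(res$reference)
  expect_lt(max(abs(crossprod(b, res$final$mode_cT$vector))), 1e-6)
})

test_that("training correlation is non-decreasing in component count", {
  set.seed(31)
  x <- matrix(rnorm(300 * 50), 300, 50)
  y <- as.numeric(x %*% rnorm(50)) + rnorm(300, 0, 3)
  fits <- vapply(1:8, function(k)
    pls_fma(x, y, n_components = k, split = NULL)$fit_r, numeric(1))
  expect_true(all(diff(fits) >= -1e-10))
})

test_that("select_components finds low-dimensional planted couplings", {
  # three predictive internal directions with distinct variances on an
  # isotropic background: the cross-validation curve peaks near 3
  set.seed(47)
  n <- 2000
  vs <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))
  scores <- sweep(matrix(rnorm(n * 3), n, 3), 2L, c(3, 2, 1), "*")
  x <- matrix(rnorm(n * 100, 0, 0.5), n, 100) + scores %*% t(vs)
  y <- rowSums(scores) + rnorm(n, 0, 0.3)
  sel <- select_components(x, y, k_max = 12)
  expect_length(sel$cv_curve, 12)
  expect_lte(sel$k_best, 5)
  expect_gte(sel$model$n_components, 1)
  # final model is refit on the full data: no cross-validation half
  expect_true(is.na(sel$model$cv_r))
  # pure-noise target: cross-validation never exceeds 0.3
  sel0 <- select_components(x, sample(y), k_max = 8)
  expect_lt(max(sel0$cv_curve, na.rm = TRUE), 0.3)
})

test_that("ensemble weighting reduces to cT for single or isotropic
           latent structure and keeps positive target correlation", {
  # single latent vector: cTew equals cT up to sign
  x <- matrix(rnorm(150 * 30), 150, 30)
  y <- as.numeric(x %*% rnorm(30)) + rnorm(150)
  m1 <- pls_fma(x, y, n_components = 1, split = NULL)
  ew1 <- ensemble_weight(m1)
  expect_equal(mode_overlap(ew1, m1$mode_cT), 1, tolerance = 1e-9)
  # exactly isotropic data: all latent variances equal, cTew parallel cT
  xi <- whitened_matrix(300, 40, seed = 5)
  yi <- as.numeric(xi %*% rnorm(40)) + rnorm(300, 0, 0.2)
  mi <- pls_fma(xi, yi, n_components = 5, split = NULL)
  ewi <- ensemble_weight(mi)
  expect_equal(mode_overlap(ewi, mi$mode_cT), 1, tolerance = 1e-8)
  # anisotropic planted data: cTew projection still tracks the target
  res <- fma_protocol(seed = 9, n_frames_each = 300L,
                      atoms_per_chain = 20L, k_max = 5L)
  ew <- ensemble_weight(res$model)
  proj <- project_mode(res$decomposition$tertiary, ew)
  qf <- remove_global_fit(res$decomposition$quaternary, res$reference)
  target <- project_mode(qf, res$cQ)
  n_train <- res$model$split_point
  expect_gt(pearson_r(proj[1:n_train], target[1:n_train]), 0)
})
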