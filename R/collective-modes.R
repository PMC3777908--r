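# Collective coordinates: PCA of the quaternary-only trajectory (-> cQ)
# and partial-least-squares functional mode analysis (PLS-FMA) of the
# tertiary-only trajectory against the cQ projection (-> cT, cTew).
#
# PLS-FMA finds the linear combination of tertiary coordinates maximally
# correlated with a scalar functional property (here: the projection onto
# cQ), using a small number of latent vectors to avoid overfitting the
# high-dimensional coordinate space; the number of components is chosen by
# split-half cross-validation.

#' Collective mode: a unit 3N-vector with a role tag
#'
#' @param vector Numeric 3N direction; normalised unless already unit.
#' @param role One of cQ, cT, cTew, TR_full, TR_tertiary, TR_quaternary,
#'   custom.
#' @param origin Optional 3N anchor (mean or reference coordinates) from
#'   which projections are measured.
#' @return Object of class `collective_mode`.
#' @export
collective_mode <- function(vector, role = "custom", origin = NULL) {
  vector <- as.numeric(vector)
  nv <- sqrt(sum(vector^2))
  if (!is.finite(nv) || nv == 0) stop("mode vector must be nonzero")
  structure(list(vector = vector / nv, role = role,
                 origin = if (is.null(origin)) NULL else as.numeric(origin)),
            class = "collective_mode")
}

#' @export
print.collective_mode <- function(x, ...) {
  cat(sprintf("collective_mode [%s], 3N = %d\n", x$role, length(x$vector)))
  invisible(x)
}

# Deterministic sign convention: the largest-magnitude component positive.
.fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Principal component analysis of a trajectory
#'
#' Eigen-decomposition of the coordinate covariance about the trajectory
#' mean (via SVD of the centred frame matrix). Frames should be globally
#' fitted to a common reference beforehand. Eigenvector signs follow the
#' convention that the largest-magnitude component is positive.
#'
#' @param traj A `qt_trajectory` with at least 2 frames.
#' @return Object of class `qt_pca`: `values` (variances in nm^2,
#'   descending), `vectors` (orthonormal 3N x k matrix), `mean` (3N),
#'   `explained` (per-mode fraction of total variance).
#' @export
traj_pca <- function(traj) {
  if (n_frames(traj) < 2L) stop("PCA requires at least 2 frames")
  mu <- colMeans(traj$xyz)
  xc <- sweep(traj$xyz, 2L, mu)
  sv <- svd(xc)
  values <- sv$d^2 / (n_frames(traj) - 1L)
  vectors <- apply(sv$v, 2L, .fix_sign)
  structure(list(values = values, vectors = vectors, mean = mu,
                 explained = values / sum(values)),
            class = "qt_pca")
}

#' @export
print.qt_pca <- function(x, ...) {
  cat(sprintf("qt_pca: %d modes; top-3 explained fractions %s\n",
              length(x$values),
              paste(sprintf("%.3f", utils::head(x$explained, 3L)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract a PCA eigenvector as a collective mode
#'
#' @param pca A `qt_pca`.
#' @param i Mode index (1 = largest variance).
#' @param role Role tag, default `"cQ"` for the first quaternary mode.
#' @param origin Anchor coordinates; default the PCA mean.
#' @return A `collective_mode`.
#' @export
pca_mode <- function(pca, i = 1L, role = "cQ", origin = pca$mean) {
  collective_mode(pca$vectors[, i], role = role, origin = origin)
}

#' Project a trajectory (or frame) onto a collective mode
#'
#' Per-frame scalar projection (x - origin) . vector, in nm.
#'
#' @param x A `qt_trajectory`, `structure_frame`, or F x 3N matrix.
#' @param mode A `collective_mode` (its origin is used; zero if absent).
#' @return Numeric vector of projections (length = frame count).
#' @export
project_mode <- function(x, mode) {
  xyz <- if (inherits(x, "qt_trajectory")) x$xyz
         else if (inherits(x, "structure_frame")) matrix(x$xyz, nrow = 1L)
         else as.matrix(x)
  if (ncol(xyz) != length(mode$vector))
    stop("dimension mismatch between coordinates and mode")
  origin <- if (is.null(mode$origin)) 0 else mode$origin
  as.numeric(sweep(xyz, 2L, origin) %*% mode$vector)
}

#' Pearson correlation between two scalar series
#'
#' Thin validated wrapper around [stats::cor()] used for fit and
#' cross-validation correlations.
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("at least 3 observations are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance series")
  stats::cor(a, b)
}

#' Absolute scalar product of two collective modes
#'
#' @param m1,m2 `collective_mode`s of equal dimension.
#' @return |m1 . m2| in [0, 1].
#' @export
mode_overlap <- function(m1, m2) {
  if (length(m1$vector) != length(m2$vector)) stop("dimension mismatch")
  abs(sum(m1$vector * m2$vector))
}

#' Matrix of mutual scalar products between collective modes
#'
#' @param modes Named list of `collective_mode`s.
#' @return Symmetric matrix of absolute scalar products (diagonal 1).
#' @export
overlap_table <- function(modes) {
  k <- length(modes)
  out <- matrix(NA_real_, k, k, dimnames = list(names(modes), names(modes)))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- mode_overlap(modes[[i]], modes[[j]])
  out
}

# Core PLS1 (NIPALS with deflation) on centred data. Returns weights W,
# loadings P, regression coefficients c per component. Stops early if the
# residual covariance vanishes.
.pls1 <- function(xc, yc, k) {
  p <- ncol(xc)
  W <- matrix(0, p, k)
  P <- matrix(0, p, k)
  cc <- numeric(k)
  x1 <- xc
  y1 <- yc
  used <- 0L
  for (j in seq_len(k)) {
    w <- crossprod(x1, y1)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14 * max(1, sqrt(sum(xc^2)))) break
    w <- w / nw
    t_ <- as.numeric(x1 %*% w)
    tt <- sum(t_^2)
    if (tt == 0) break
    pj <- crossprod(x1, t_) / tt
    cj <- sum(y1 * t_) / tt
    x1 <- x1 - tcrossprod(t_, pj)
    y1 <- y1 - cj * t_
    W[, j] <- w
    P[, j] <- pj
    cc[j] <- cj
    used <- j
  }
  if (used == 0L) stop("no PLS component could be extracted")
  list(W = W[, seq_len(used), drop = FALSE],
       P = P[, seq_len(used), drop = FALSE],
       c = cc[seq_len(used)], n_components = used)
}

# Latent scores of new (centred) data for all components, via deflation
# with the training weights/loadings. Returns an n x k score matrix.
.pls1_scores <- function(xc, W, P) {
  k <- ncol(W)
  scores <- matrix(0, nrow(xc), k)
  x1 <- xc
  for (j in seq_len(k)) {
    t_ <- as.numeric(x1 %*% W[, j])
    scores[, j] <- t_
    x1 <- x1 - tcrossprod(t_, P[, j])
  }
  scores
}

#' Partial-least-squares functional mode analysis
#'
#' Builds latent vectors in the (tertiary) coordinate space maximising
#' covariance with the scalar target, regresses the target on the latent
#' projections, and composes the coordinate-space gradient of the fitted
#' linear model as the collective coordinate cT. By default the model is
#' constructed on the first half of the frames and the Pearson correlation
#' of its predictions on the second half is reported as the
#' cross-validation correlation.
#'
#' @param coords Tertiary-only `qt_trajectory` (or F x 3N matrix).
#' @param target Numeric per-frame functional property (e.g. the cQ
#'   projection from [project_mode()]), same length as the frame count.
#' @param n_components Number of latent vectors (>= 1, < training frames).
#' @param split Fraction of frames used for model construction (first
#'   part); `NULL` fits on all frames and reports no cross-validation.
#' @return Object of class `qt_plsfma`: latent weights/loadings, rotation
#'   vectors, regression coefficients, `n_components`, `mode_cT`
#'   (`collective_mode`), `fit_r`, `cv_r`, `split_point`, per-component
#'   coefficients and variances used for ensemble weighting, and centring
#'   information.
#' @export
pls_fma <- function(coords, target, n_components, split = 0.5) {
  xyz <- if (inherits(coords, "qt_trajectory")) coords$xyz else as.matrix(coords)
  target <- as.numeric(target)
  nf <- nrow(xyz)
  if (length(target) != nf) stop("target length must equal frame count")
  if (stats::sd(target) == 0) stop("target has zero variance")
  if (n_components < 1L) stop("n_components must be >= 1")
  if (is.null(split)) {
    train <- seq_len(nf)
    val <- integer(0)
  } else {
    split_point <- floor(nf * split)
    if (split_point < 3L || nf - split_point < 3L)
      stop("too few frames on one side of the split")
    train <- seq_len(split_point)
    val <- (split_point + 1L):nf
  }
  if (n_components > length(train) - 1L)
    stop("n_components must be at most training frames - 1")
  xbar <- colMeans(xyz[train, , drop = FALSE])
  ybar <- mean(target[train])
  xc <- sweep(xyz[train, , drop = FALSE], 2L, xbar)
  yc <- target[train] - ybar
  fit <- .pls1(xc, yc, n_components)
  # rotation vectors: columns of R = W (P^T W)^{-1}; beta = R c
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  beta <- as.numeric(R %*% fit$c)
  rnorm_ <- sqrt(colSums(R^2))
  rhat <- sweep(R, 2L, rnorm_, "/")
  # data variance along each (normalised) latent direction, training set
  sigma2 <- apply(xc %*% rhat, 2L, stats::var)
  pred_train <- ybar + as.numeric(xc %*% beta)
  fit_r <- pearson_r(pred_train, target[train])
  cv_r <- NA_real_
  if (length(val) > 0L) {
    xv <- sweep(xyz[val, , drop = FALSE], 2L, xbar)
    pred_val <- ybar + as.numeric(xv %*% beta)
    cv_r <- pearson_r(pred_val, target[val])
  }
  structure(list(
    weights = fit$W, loadings = fit$P, rotations = R, coefs = fit$c,
    beta = beta, n_components = fit$n_components,
    mode_cT = collective_mode(beta, role = "cT", origin = xbar),
    fit_r = fit_r, cv_r = cv_r,
    split_point = if (is.null(split)) nf else length(train),
    ew_coefs = fit$c * rnorm_, ew_sigma2 = sigma2, ew_dirs = rhat,
    xbar = xbar, ybar = ybar),
    class = "qt_plsfma")
}

#' @export
print.qt_plsfma <- function(x, ...) {
  cat(sprintf("qt_plsfma: %d components, fit_r = %.3f, cv_r = %s\n",
              x$n_components, x$fit_r,
              if (is.na(x$cv_r)) "NA" else sprintf("%.3f", x$cv_r)))
  invisible(x)
}

#' Choose the number of PLS components by cross-validation
#'
#' Fits models with 1..k_max latent vectors on the first split of the
#' frames, evaluates the cross-validation correlation on the second split
#' for each component count, selects the maximiser, and refits the final
#' model with that count on the full data set.
#'
#' @inheritParams pls_fma
#' @param k_max Largest component count to consider.
#' @return List with `k_best`, `cv_curve` (length k_max; NA past the last
#'   extractable component), `model` (final `qt_plsfma` refit on all
#'   frames with `k_best` components) and `split_model` (the split-half
#'   model at `k_best`).
#' @export
select_components <- function(coords, target, k_max, split = 0.5) {
  xyz <- if (inherits(coords, "qt_trajectory")) coords$xyz else as.matrix(coords)
  target <- as.numeric(target)
  nf <- nrow(xyz)
  split_point <- floor(nf * split)
  train <- seq_len(split_point)
  val <- (split_point + 1L):nf
  xbar <- colMeans(xyz[train, , drop = FALSE])
  ybar <- mean(target[train])
  xc <- sweep(xyz[train, , drop = FALSE], 2L, xbar)
  yc <- target[train] - ybar
  fit <- .pls1(xc, yc, min(k_max, length(train) - 1L))
  xv <- sweep(xyz[val, , drop = FALSE], 2L, xbar)
  sc_val <- .pls1_scores(xv, fit$W, fit$P)
  cv_curve <- rep(NA_real_, k_max)
  pred <- rep(ybar, length(val))
  for (k in seq_len(fit$n_components)) {
    pred <- pred + fit$c[k] * sc_val[, k]
    cv_curve[k] <- pearson_r(pred, target[val])
  }
  k_best <- which.max(cv_curve)
  list(k_best = k_best, cv_curve = cv_curve,
       model = pls_fma(xyz, target, k_best, split = NULL),
       split_model = pls_fma(xyz, target, k_best, split = split))
}

#' Ensemble-weighted collective mode (cTew)
#'
#' Reweights the latent vectors underlying cT by their contribution to the
#' overall coordinate variance: cTew = normalise(sum_k c_k sigma2_k v_k),
#' where v_k are the unit latent directions in coordinate space, c_k their
#' regression coefficients and sigma2_k the data variance along v_k. While
#' cT is the maximally correlated motion, cTew emphasises the most
#' probable motion that correlates with the functional property.
#'
#' @param model A fitted `qt_plsfma`.
#' @param coords Optional trajectory on which to recompute the per-latent
#'   variances; defaults to the variances stored at fit time.
#' @return A `collective_mode` with role `"cTew"`.
#' @export
ensemble_weight <- function(model, coords = NULL) {
  sigma2 <- model$ew_sigma2
  if (!is.null(coords)) {
    xyz <- if (inherits(coords, "qt_trajectory")) coords$xyz else as.matrix(coords)
    xc <- sweep(xyz, 2L, model$xbar)
    sigma2 <- apply(xc %*% model$ew_dirs, 2L, stats::var)
  }
  v <- as.numeric(model$ew_dirs %*% (model$ew_coefs * sigma2))
  collective_mode(v, role = "cTew", origin = model$xbar)
}
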