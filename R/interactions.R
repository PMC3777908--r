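# Inter-chain interactions: van der Waals overlap scoring and
# distance-based residue contacts along the cQ -> cTew path.
#
# Only atom pairs on *different* partition groups are ever counted;
# intra-chain pairs are ignored throughout. All distances in nm. Contact
# detection offers a brute-force all-pairs search and a cell-list
# accelerated search that returns identical results (the brute-force path
# doubles as the test oracle).

# All inter-chain atom pairs closer than `cutoff` (strict <).
# Returns data.frame(i, j, d) with i < j.
.pairs_brute <- function(mat, chain_id, cutoff) {
  nc <- length(unique(chain_id))
  groups <- split(seq_len(nrow(mat)), chain_id)
  out <- list()
  gi <- seq_along(groups)
  for (a in gi) {
    for (b in gi[gi > a]) {
      ia <- groups[[a]]
      ib <- groups[[b]]
      xa <- mat[ia, , drop = FALSE]
      xb <- mat[ib, , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        i <- ia[hit[, 1]]
        j <- ib[hit[, 2]]
        sw <- i > j
        out[[length(out) + 1L]] <- data.frame(
          i = ifelse(sw, j, i), j = ifelse(sw, i, j),
          d = sqrt(pmax(d2[hit], 0)))
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      d = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$i, res$j), , drop = FALSE]
}

# Cell-list search: bin atoms into cubic cells of edge `cutoff`, compare
# each atom only against atoms in its 27 neighbouring cells.
.pairs_cells <- function(mat, chain_id, cutoff) {
  lo <- apply(mat, 2L, min)
  ci <- floor(sweep(mat, 2L, lo) / cutoff)
  nx <- max(ci[, 1]) + 1L
  ny <- max(ci[, 2]) + 1L
  key <- ci[, 1] + nx * (ci[, 2] + ny * ci[, 3])
  cells <- split(seq_len(nrow(mat)), key)
  ckey <- as.numeric(names(cells))
  ccoord <- cbind(ckey %% nx, (ckey %/% nx) %% ny, ckey %/% (nx * ny))
  lookup <- new.env(hash = TRUE, size = length(cells))
  for (k in seq_along(cells)) assign(as.character(ckey[k]), k, envir = lookup)
  out <- list()
  for (k in seq_along(cells)) {
    ia <- cells[[k]]
    # neighbours with key >= this cell's key to visit each cell pair once
    nb <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      cc <- ccoord[k, ] + c(dx, dy, dz)
      if (any(cc < 0) || cc[1] >= nx || cc[2] >= ny) next
      kk <- cc[1] + nx * (cc[2] + ny * cc[3])
      if (kk < ckey[k]) next
      idx <- lookup[[as.character(kk)]]
      if (!is.null(idx)) nb <- c(nb, idx)
    }
    for (k2 in nb) {
      ib <- cells[[k2]]
      xa <- mat[ia, , drop = FALSE]
      xb <- mat[ib, , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (!nrow(hit)) next
      i <- ia[hit[, 1]]
      j <- ib[hit[, 2]]
      keep <- if (k2 == k) i < j else rep(TRUE, length(i))
      keep <- keep & chain_id[i] != chain_id[j]
      if (!any(keep)) next
      i <- i[keep]
      j <- j[keep]
      sw <- i > j
      out[[length(out) + 1L]] <- data.frame(
        i = ifelse(sw, j, i), j = ifelse(sw, i, j),
        d = sqrt(pmax(d2[hit][keep], 0)))
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      d = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[chain_id[res$i] != chain_id[res$j], , drop = FALSE]
  res[order(res$i, res$j), , drop = FALSE]
}

#' Inter-chain atom pairs within a distance cutoff
#'
#' @param frame A `structure_frame`.
#' @param partition Chain partition (default the frame's).
#' @param cutoff Distance cutoff in nm (strict `<`).
#' @param method `"cells"` (cell-list accelerated) or `"brute"`
#'   (all-pairs); both return identical results.
#' @return data.frame with columns i, j (atom indices, i < j, different
#'   chains) and d (distance in nm), sorted by (i, j).
#' @export
interchain_pairs <- function(frame, partition = frame$partition,
                             cutoff, method = c("cells", "brute")) {
  method <- match.arg(method)
  if (length(partition) < 2L) stop("need at least 2 chains")
  if (cutoff <= 0) stop("cutoff must be positive")
  mat <- xyz_mat(frame$xyz)
  chain_id <- integer(nrow(mat))
  for (ci in seq_along(partition)) chain_id[partition[[ci]]] <- ci
  if (method == "brute") .pairs_brute(mat, chain_id, cutoff)
  else .pairs_cells(mat, chain_id, cutoff)
}

#' Inter-chain van der Waals overlap of a structure
#'
#' For every unordered atom pair (i, j) on different chains, the
#' penetration depth p_ij = max(0, r_i + r_j - d_ij) is computed; the total
#' is the sum over pairs, a length in nm measuring how energetically
#' unfavourable the steric interface is. A clash-free structure scores
#' exactly 0. With `double_count = TRUE` the per-atom accounting (each
#' pair attributed to both atoms, so summed twice) is used for the total.
#'
#' @param frame A `structure_frame` with radii populated.
#' @param partition Chain partition (>= 2 groups).
#' @param per_atom Also return the per-atom overlap contributions (each
#'   pair contributes its penetration to both atoms).
#' @param double_count Use the per-atom (pair-doubled) total.
#' @param method Pair search method, see [interchain_pairs()].
#' @return Object of class `qt_overlap`: `total` (nm), `pairs`
#'   (data.frame i, j, d, penetration), optionally `per_atom`.
#' @export
vdw_overlap <- function(frame, partition = frame$partition,
                        per_atom = FALSE, double_count = FALSE,
                        method = c("cells", "brute")) {
  radius <- frame$atoms$radius
  if (is.null(radius) || anyNA(radius)) {
    bad <- which(is.na(radius))
    stop(sprintf("missing vdW radius for atom(s) %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  pairs <- interchain_pairs(frame, partition, cutoff = 2 * max(radius),
                            method = match.arg(method))
  pen <- pmax(0, radius[pairs$i] + radius[pairs$j] - pairs$d)
  keep <- pen > 0
  pairs <- pairs[keep, , drop = FALSE]
  pairs$penetration <- pen[keep]
  total <- sum(pairs$penetration)
  out <- list(total = if (double_count) 2 * total else total,
              pairs = pairs, double_count = double_count)
  if (per_atom) {
    pa <- numeric(n_atoms(frame))
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        pa[pairs$i[k]] <- pa[pairs$i[k]] + pairs$penetration[k]
        pa[pairs$j[k]] <- pa[pairs$j[k]] + pairs$penetration[k]
      }
    }
    out$per_atom <- pa
  }
  structure(out, class = "qt_overlap")
}

#' @export
print.qt_overlap <- function(x, ...) {
  cat(sprintf("qt_overlap: total %.4f nm over %d penetrating pair(s)%s\n",
              x$total, nrow(x$pairs),
              if (x$double_count) " (per-atom double counting)" else ""))
  invisible(x)
}

#' Van der Waals overlap over all cells of a coupling grid
#'
#' Computes the inter-chain overlap of the backprojected structure at every
#' grid cell, yielding the overlap landscape on the (cQ, cTew) plane.
#'
#' @param grid A `qt_grid` (or a list of `structure_frame`s with a
#'   `dim_grid` attribute as returned by [grid_structures()]).
#' @param partition Chain partition; default from the structures.
#' @param ... Passed to [vdw_overlap()].
#' @return n x n numeric matrix; rows index the cQ (a) axis, columns the
#'   cTew (b) axis.
#' @export
overlap_surface <- function(grid, partition = NULL, ...) {
  structures <- if (inherits(grid, "qt_grid")) grid_structures(grid) else grid
  dg <- attr(structures, "dim_grid")
  if (is.null(dg)) dg <- c(length(structures), 1L)
  vals <- vapply(structures, function(fr) {
    part <- if (is.null(partition)) fr$partition else partition
    vdw_overlap(fr, part, ...)$total
  }, numeric(1))
  matrix(vals, nrow = dg[1], ncol = dg[2])
}

.residue_key <- function(atoms, i) {
  paste(atoms$chain[i], atoms$resno[i], atoms$resid[i], sep = "/")
}

#' Inter-chain residue contacts of a structure
#'
#' A residue pair (on different chains) is in contact iff any pair of their
#' heavy atoms is closer than `cutoff` (default 0.3 nm).
#'
#' @param frame A `structure_frame`.
#' @param partition Chain partition.
#' @param cutoff Contact cutoff in nm.
#' @param method Pair search method, see [interchain_pairs()].
#' @return data.frame with columns res_a, res_b (keys "chain/resno/resid",
#'   res_a < res_b lexicographically by chain then number) and min_dist.
#' @export
find_contacts <- function(frame, partition = frame$partition, cutoff = 0.3,
                          method = c("cells", "brute")) {
  heavy <- !(toupper(frame$atoms$element) %in% c("H", "D"))
  pairs <- interchain_pairs(frame, partition, cutoff, match.arg(method))
  pairs <- pairs[heavy[pairs$i] & heavy[pairs$j], , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(res_a = character(0), res_b = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  at <- frame$atoms
  ka <- .residue_key(at, pairs$i)
  kb <- .residue_key(at, pairs$j)
  ord <- paste(at$chain[pairs$i], sprintf("%08d", at$resno[pairs$i])) >
         paste(at$chain[pairs$j], sprintf("%08d", at$resno[pairs$j]))
  res_a <- ifelse(ord, kb, ka)
  res_b <- ifelse(ord, ka, kb)
  agg <- stats::aggregate(pairs$d, by = list(res_a = res_a, res_b = res_b),
                          FUN = min)
  names(agg)[3] <- "min_dist"
  agg[order(agg$res_a, agg$res_b), , drop = FALSE]
}

#' Contact presence profiles along a coupling path
#'
#' Detects inter-chain residue contacts in every backprojected structure of
#' the path and assembles, for every residue pair observed at least once, a
#' presence vector over all path cells.
#'
#' @param path A `qt_path`.
#' @param partition Chain partition; default from the path structures.
#' @param cutoff Contact cutoff in nm (default 0.3).
#' @param method Pair search method.
#' @return Object of class `qt_contacts`: `pairs` (data.frame res_a,
#'   res_b), `presence` (K x L logical matrix, one row per pair, one
#'   column per path cell), `path_length`, `corner`.
#' @export
contact_profile <- function(path, partition = NULL, cutoff = 0.3,
                            method = c("cells", "brute")) {
  method <- match.arg(method)
  L <- length(path$structures)
  if (L == 0L) stop("empty path")
  per_cell <- lapply(path$structures, function(fr) {
    part <- if (is.null(partition)) fr$partition else partition
    find_contacts(fr, part, cutoff, method)
  })
  keys <- unique(unlist(lapply(per_cell, function(d)
    paste(d$res_a, d$res_b, sep = "|"))))
  if (is.null(keys)) keys <- character(0)
  presence <- matrix(FALSE, nrow = length(keys), ncol = L)
  rownames(presence) <- keys
  for (l in seq_len(L)) {
    k <- paste(per_cell[[l]]$res_a, per_cell[[l]]$res_b, sep = "|")
    presence[match(k, keys), l] <- TRUE
  }
  sp <- strsplit(keys, "|", fixed = TRUE)
  pairs <- data.frame(res_a = vapply(sp, `[`, "", 1L),
                      res_b = vapply(sp, `[`, "", 2L),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, presence = presence, path_length = L,
                 corner = path$corner),
            class = "qt_contacts")
}

#' @export
print.qt_contacts <- function(x, ...) {
  cat(sprintf("qt_contacts: %d residue pair(s) over %d path cells\n",
              nrow(x$pairs), x$path_length))
  if (!is.null(x$pairs$class)) print(table(x$pairs$class))
  invisible(x)
}

# Segment scheme for classification: disjoint T-end, elbow (around the
# path corner) and R-end index sets. Defaults shrink on short paths so the
# segments stay disjoint; on a 17-cell path they are first 3 / corner +-2 /
# last 3 cells.
.path_segments <- function(L, corner, end_width = NULL,
                           elbow_halfwidth = NULL) {
  if (is.null(end_width)) end_width <- min(3L, max(1L, L %/% 4L))
  if (is.null(elbow_halfwidth))
    elbow_halfwidth <- min(2L, max(0L, (L - 1L) %/% 6L))
  t_seg <- seq_len(end_width)
  r_seg <- (L - end_width + 1L):L
  e_seg <- max(1L, corner - elbow_halfwidth):min(L, corner + elbow_halfwidth)
  if (length(intersect(t_seg, e_seg)) || length(intersect(r_seg, e_seg)) ||
      length(intersect(t_seg, r_seg)))
    stop("path too short for the requested segment scheme")
  list(t = t_seg, elbow = e_seg, r = r_seg)
}

#' Classify contacts along the cQ -> cTew path
#'
#' Assigns each residue-pair profile a mechanistic class based on where
#' along the path the contact is present. With T-end, elbow (corner) and
#' R-end segments:
#' \describe{
#'   \item{static}{present in every path cell;}
#'   \item{pulling}{present at both end segments, absent throughout the
#'     elbow — partners hold on near the end states and are torn apart in
#'     the off-diagonal intermediate states;}
#'   \item{pushing}{absent at both ends, present in the elbow — partners
#'     meet only in the off-diagonal intermediate states;}
#'   \item{switching}{a residue whose contact-partner set at the T-end
#'     differs from that at the R-end (at least one partner at each end):
#'     its end-specific contacts are marked switching;}
#'   \item{other}{any remaining pattern.}
#' }
#'
#' @param contacts A `qt_contacts` from [contact_profile()].
#' @param end_width Cells in each end segment; default adapts to the path
#'   length (3 on typical ~17-cell paths).
#' @param elbow_halfwidth Half-width of the elbow segment around the
#'   corner; default adapts (2 on typical ~17-cell paths).
#' @return The `qt_contacts` with a `class` column added to `$pairs` and
#'   the segment scheme stored as `$segments`.
#' @export
classify_contacts <- function(contacts, end_width = NULL,
                              elbow_halfwidth = NULL) {
  L <- contacts$path_length
  seg <- .path_segments(L, contacts$corner, end_width, elbow_halfwidth)
  pr <- contacts$presence
  k <- nrow(pr)
  at_t <- apply(pr[, seg$t, drop = FALSE], 1L, any)
  at_r <- apply(pr[, seg$r, drop = FALSE], 1L, any)
  at_e <- apply(pr[, seg$elbow, drop = FALSE], 1L, any)
  cls <- rep("other", k)
  cls[at_t & at_r & !at_e] <- "pulling"
  cls[!at_t & !at_r & at_e] <- "pushing"
  cls[apply(pr, 1L, all)] <- "static"
  # switching: residue-level partner comparison between the two ends
  if (k) {
    res <- unique(c(contacts$pairs$res_a, contacts$pairs$res_b))
    for (r in res) {
      ra <- contacts$pairs$res_a == r
      rb <- contacts$pairs$res_b == r
      partner <- ifelse(ra, contacts$pairs$res_b, contacts$pairs$res_a)
      inv <- ra | rb
      pt <- partner[inv & at_t]
      pv <- partner[inv & at_r]
      if (length(pt) && length(pv) && !setequal(pt, pv)) {
        swap <- inv & (xor(at_t, at_r)) & cls == "other"
        cls[swap] <- "switching"
      }
    }
  }
  contacts$pairs$class <- cls
  contacts$segments <- seg
  contacts
}
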