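# Structure and trajectory input/output.
#
# PDB reading and writing is delegated to bio3d; coordinates are converted
# from Angstrom to nm on read (and back on write). Trajectories can also be
# stored in a plain-text array container (.qtj) holding the atom table and
# an F x 3N coordinate block, which round-trips exactly at full double
# precision.

#' Read a structure (or multi-model trajectory) from a PDB file
#'
#' Chain identifiers define the default partition. Hydrogens are dropped by
#' default, matching the heavy-atom analyses in the rest of the package.
#'
#' @param file Path to a PDB file.
#' @param multi If `TRUE`, read all MODEL records and return a
#'   `qt_trajectory`; otherwise the first model as a `structure_frame`.
#' @param drop_hydrogens Drop atoms with element H/D at load time.
#' @param radii Element-to-radius table (nm), see [default_radii()].
#' @return A `structure_frame` or, with `multi = TRUE`, a `qt_trajectory`.
#' @export
read_structure_pdb <- function(file, multi = FALSE, drop_hydrogens = TRUE,
                               radii = default_radii()) {
  pdb <- bio3d::read.pdb(file, multi = multi, verbose = FALSE)
  at <- pdb$atom
  ele <- toupper(trimws(at$elesy))
  miss <- is.na(ele) | ele == ""
  if (any(miss)) ele[miss] <- toupper(bio3d::atom2ele(at$elety[miss]))
  keep <- rep(TRUE, nrow(at))
  if (drop_hydrogens) keep <- !(ele %in% c("H", "D"))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- atom_table(element = ele[keep], chain = chain[keep],
                      resno = at$resno[keep], resid = at$resid[keep],
                      name = at$elety[keep], radii = radii)
  sel <- as.vector(t(outer(which(keep), c(1L, 2L, 3L),
                           function(i, k) 3L * (i - 1L) + k)))
  if (multi && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L) {
    trajectory(pdb$xyz[, sel, drop = FALSE] / 10, atoms, provenance = "raw")
  } else {
    xyz <- as.numeric(pdb$xyz)[sel]
    structure_frame(xyz / 10, atoms, provenance = "raw")
  }
}

.as_bio3d_xyz <- function(x) {
  # nm -> Angstrom, flat or matrix
  x * 10
}

#' Write a structure frame or trajectory to a PDB file
#'
#' Trajectories are written as multi-model PDB files (one MODEL per frame).
#' Coordinates are converted from nm to Angstrom.
#'
#' @param x A `structure_frame` or `qt_trajectory`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_structure_pdb <- function(x, file) {
  atoms <- x$atoms
  xyz <- if (inherits(x, "qt_trajectory")) x$xyz else matrix(x$xyz, nrow = 1L)
  bio3d::write.pdb(file = file, xyz = .as_bio3d_xyz(xyz),
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resid,
                   chain = atoms$chain, elety = atoms$name,
                   eleno = seq_len(nrow(atoms)))
  invisible(file)
}

#' Write / read the plain-text trajectory container (.qtj)
#'
#' A self-contained text format: a JSON header line (frame count, atom
#' count, provenance, optional times), the atom table, and one
#' whitespace-separated row of 3N coordinates (nm) per frame. Values are
#' written with full double precision, so write/read round-trips exactly.
#'
#' @param traj A `qt_trajectory`.
#' @param file Path to the container file.
#' @return `write_trajectory()` invisibly returns `file`;
#'   `read_trajectory()` returns a `qt_trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  hdr <- list(format = "qtcouple-trajectory-v1",
              n_frames = n_frames(traj), n_atoms = n_atoms(traj),
              provenance = traj$provenance)
  if (!is.null(traj$times)) hdr$times <- traj$times
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  writeLines("@atoms", con)
  utils::write.table(traj$atoms, con, row.names = FALSE, quote = TRUE)
  writeLines("@coords", con)
  utils::write.table(format(traj$xyz, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  hdr <- jsonlite::fromJSON(lines[1L])
  if (!identical(hdr$format, "qtcouple-trajectory-v1"))
    stop("not a qtcouple trajectory container")
  ia <- which(lines == "@atoms")[1L]
  ic <- which(lines == "@coords")[1L]
  atoms <- utils::read.table(text = lines[(ia + 1L):(ic - 1L)], header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(chain = "character"))
  xyz <- as.matrix(utils::read.table(text = lines[(ic + 1L):length(lines)]))
  dimnames(xyz) <- NULL
  trajectory(xyz, atoms, times = hdr$times, provenance = hdr$provenance)
}

#' Export / import a collective mode as JSON
#'
#' Stores the unit 3N-vector, its role tag and its origin (anchoring
#' structure coordinates) at full precision.
#'
#' @param mode A `collective_mode`.
#' @param file Path to the JSON file.
#' @return `write_mode()` invisibly returns `file`; `read_mode()` a
#'   `collective_mode`.
#' @export
write_mode <- function(mode, file) {
  jsonlite::write_json(list(role = mode$role, vector = mode$vector,
                            origin = mode$origin),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_mode
#' @export
read_mode <- function(file) {
  x <- jsonlite::fromJSON(file)
  collective_mode(x$vector, role = x$role, origin = x$origin)
}

#' Write a "mode movie": interpolated structures along a collective mode
#'
#' Writes a multi-model PDB interpolating origin + s * amplitude * mode for
#' s in [-1, 1], a standard way to visualise a collective coordinate.
#'
#' @param mode A `collective_mode`.
#' @param frame A `structure_frame` providing the atom table (and origin if
#'   the mode has none).
#' @param file Output PDB path.
#' @param amplitude Half-range of the interpolation in nm.
#' @param n_steps Number of models.
#' @return Invisibly, `file`.
#' @export
write_mode_movie <- function(mode, frame, file, amplitude = 0.5,
                             n_steps = 11L) {
  origin <- if (!is.null(mode$origin)) mode$origin else frame$xyz
  s <- seq(-1, 1, length.out = n_steps)
  xyz <- t(vapply(s, function(si) origin + si * amplitude * mode$vector,
                  numeric(length(origin))))
  write_structure_pdb(trajectory(xyz, frame$atoms, frame$partition,
                                 provenance = "backprojected"), file)
}
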