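# Element-wise van der Waals radii (nm) and masses (u).
#
# Radii follow Bondi's compilation where available; metals use commonly
# adopted values. The table is deliberately user-replaceable: every reader
# accepts a `radii` argument and read_radius_table() parses a two-column
# text file (element, radius in nm).

.default_radii <- c(
  H = 0.120, D = 0.120, C = 0.170, N = 0.155, O = 0.152, F = 0.147,
  P = 0.180, S = 0.180, CL = 0.175, BR = 0.185, I = 0.198,
  FE = 0.194, ZN = 0.139, CU = 0.140, MG = 0.173, MN = 0.197,
  "NA" = 0.227, K = 0.275, CA = 0.231, SE = 0.190, B = 0.192
)

.default_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, CU = 63.546, MG = 24.305, MN = 54.938,
  "NA" = 22.990, K = 39.098, CA = 40.078, SE = 78.971, B = 10.81
)

# Residue names treated as solvent or monoatomic ions by the default
# heavy-atom selection policy (protein + prosthetic groups).
.solvent_resids <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "TIP4", "DOD", "H2O")
.ion_resids <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "CU", "IOD", "BR",
                 "SO4", "PO4", "NO3")

#' Default van der Waals radius table
#'
#' Named numeric vector of per-element van der Waals radii in nm used when a
#' structure is built without explicit radii. Bondi-style values; replace via
#' the `radii` argument of [read_structure_pdb()] / [structure_frame()] or
#' with [read_radius_table()].
#'
#' @return Named numeric vector, names are upper-case element symbols.
#' @export
#' @examples
#' default_radii()[c("C", "N", "O")]
default_radii <- function() .default_radii

#' Read a van der Waals radius table from a text file
#'
#' The file has two whitespace-separated columns: element symbol and radius
#' in nm. Lines starting with `#` are ignored.
#'
#' @param file Path to the table.
#' @return Named numeric vector of radii in nm.
#' @export
read_radius_table <- function(file) {
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("element", "radius"),
                           stringsAsFactors = FALSE)
  if (any(!is.finite(tab$radius)) || any(tab$radius <= 0))
    stop("radius table contains non-positive or non-finite radii")
  stats::setNames(tab$radius, toupper(tab$element))
}

# Look up per-atom values from an element-keyed table; error listing the
# offending atoms if an element is unknown.
.element_lookup <- function(elements, table, what = "radius") {
  key <- toupper(trimws(elements))
  out <- unname(table[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop(sprintf("no %s for element(s): %s (atoms %s)", what,
                 paste(bad, collapse = ", "),
                 paste(utils::head(which(is.na(out)), 10L), collapse = ", ")))
  }
  out
}
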