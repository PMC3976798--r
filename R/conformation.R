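# The conformation container: a residue sequence plus a self-avoiding walk,
# one lattice point per residue.

.aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL")

.aa_one <- structure(names(.aa_three), names = .aa_three)

#' Construct a lattice conformation
#'
#' Pairs a residue sequence (one-letter amino-acid codes, or an H/P string)
#' with a self-avoiding walk on the FCC lattice, one point per residue.
#'
#' @param sequence Single string; residues in one-letter code (H/P strings
#'   are allowed, see [spiral_search()] for how they are interpreted).
#' @param coords An n x 3 integer matrix, n = `nchar(sequence)`.
#' @param validate Check the self-avoiding-walk invariant (default `TRUE`).
#'   Skipping validation is intended for internal hot paths only.
#' @return An object of class `fcc_conformation`: a list with elements
#'   `sequence` and `coords`.
#' @examples
#' conformation("HPPH", rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
#' @export
conformation <- function(sequence, coords, validate = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  coords <- .as_coord_matrix(coords)
  if (nchar(sequence) != nrow(coords))
    stop("sequence length (", nchar(sequence), ") does not match number of ",
         "coordinates (", nrow(coords), ")")
  if (validate && !is_self_avoiding_walk(coords))
    stop("coordinates are not a valid self-avoiding walk on the FCC lattice")
  structure(list(sequence = sequence, coords = coords),
            class = "fcc_conformation")
}

#' @export
print.fcc_conformation <- function(x, ...) {
  n <- nrow(x$coords)
  cat("FCC lattice conformation:", n, "residues\n")
  seq_show <- if (n > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat("  sequence: ", seq_show, "\n", sep = "")
  mv <- encode_absolute(x$coords)
  mv_show <- if (nchar(mv) > 60) paste0(substr(mv, 1, 57), "...") else mv
  cat("  moves:    ", mv_show, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.fcc_conformation <- function(x, ...) {
  data.frame(residue = strsplit(x$sequence, "")[[1]],
             x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
}

#' Write / read a conformation in the plain-text interchange format
#'
#' Line 1 holds the sequence, line 2 the absolute move string (`A`..`L`,
#' empty for single-residue chains), and optional following lines
#' `i x y z` give integer coordinates. `read_conformation()` reconstructs
#' the walk from the move string (coordinate lines, when present, are
#' cross-checked).
#'
#' @param conf An `fcc_conformation`.
#' @param path File path.
#' @param coords Also write explicit coordinate lines (default `TRUE`).
#' @return `write_conformation()` returns `path` invisibly;
#'   `read_conformation()` returns an `fcc_conformation`.
#' @export
write_conformation <- function(conf, path, coords = TRUE) {
  stopifnot(inherits(conf, "fcc_conformation"))
  lines <- c(conf$sequence, encode_absolute(conf$coords))
  if (coords) {
    lines <- c(lines, paste(seq_len(nrow(conf$coords)),
                            conf$coords[, 1], conf$coords[, 2], conf$coords[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("conformation file needs at least 2 lines")
  sequence <- toupper(trimws(lines[1]))
  moves <- toupper(trimws(lines[2]))
  xyz <- decode_absolute(moves)
  if (length(lines) > 2L) {
    tab <- utils::read.table(text = lines[-(1:2)])
    if (ncol(tab) != 4L) stop("coordinate lines must be 'i x y z'")
    given <- .as_coord_matrix(as.matrix(tab[order(tab[[1]]), 2:4]))
    xyz <- decode_absolute(moves, origin = given[1, ])
    if (!identical(unname(given), unname(xyz)))
      stop("coordinate lines disagree with the move string")
  }
  conformation(sequence, xyz)
}

#' Export a conformation as a CA-trace PDB file
#'
#' Writes one CA atom per residue, with lattice coordinates scaled so that
#' consecutive residues are 3.8 Angstrom apart (FCC unit neighbours are
#' sqrt(2) lattice units apart, hence the default factor 3.8 / sqrt(2)).
#' Uses the bio3d package for the PDB format.
#'
#' @param conf An `fcc_conformation` with a standard amino-acid sequence.
#' @param path Output PDB path.
#' @param scale Angstrom per lattice unit (default `3.8 / sqrt(2)`).
#' @return `path`, invisibly.
#' @export
export_pdb <- function(conf, path, scale = 3.8 / sqrt(2)) {
  stopifnot(inherits(conf, "fcc_conformation"))
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("export_pdb() requires the bio3d package")
  res1 <- strsplit(conf$sequence, "")[[1]]
  res3 <- .aa_three[res1]
  if (anyNA(res3))
    stop("sequence contains non-standard residue letters: ",
         paste(unique(res1[is.na(res3)]), collapse = ", "))
  xyz <- as.vector(t(conf$coords * scale))
  n <- length(res1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = seq_len(n),
                   resid = unname(res3), elety = rep("CA", n),
                   chain = rep("A", n))
  invisible(path)
}
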