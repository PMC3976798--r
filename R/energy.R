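# Conformation energy models: HP contact counting and the Berrera et al.
# 20x20 empirical contact-potential sum. Both count only nonconsecutive
# residue pairs at unit lattice distance (squared Euclidean distance 2).

.pkg_cache <- new.env(parent = emptyenv())

# Hydrophobic residues: Gly, Ala, Pro, Val, Leu, Ile, Met, Phe, Tyr, Trp.
.hp_hydrophobic <- c("G", "A", "P", "V", "L", "I", "M", "F", "Y", "W")
.hp_polar       <- c("S", "T", "C", "N", "Q", "K", "H", "R", "D", "E")

#' Classify an amino-acid sequence into H/P categories
#'
#' Maps the ten hydrophobic residues (Gly, Ala, Pro, Val, Leu, Ile, Met,
#' Phe, Tyr, Trp) to `H` and the ten polar residues (Ser, Thr, Cys, Asn,
#' Gln, Lys, His, Arg, Asp, Glu) to `P`.
#'
#' @param seq Single string over the 20 standard one-letter codes
#'   (lower case accepted). Nonstandard letters (B, Z, X, ...) are rejected.
#' @return A string over `{H, P}` of the same length.
#' @examples
#' classify_hp("GAPVLIMFYW")  # all H
#' classify_hp("MK")          # "HP"
#' @export
classify_hp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  letters_vec <- strsplit(toupper(seq), "")[[1]]
  if (length(letters_vec) == 0L) stop("sequence must be nonempty")
  out <- ifelse(letters_vec %in% .hp_hydrophobic, "H",
                ifelse(letters_vec %in% .hp_polar, "P", NA_character_))
  if (anyNA(out))
    stop("unknown residue letter(s): ",
         paste(unique(letters_vec[is.na(out)]), collapse = ", "))
  paste(out, collapse = "")
}

# Load the lower-triangular contact-potential table and mirror it into a
# full symmetric 20x20 matrix, dimnames = one-letter codes in file row order.
.bm_load <- function() {
  if (!is.null(.pkg_cache$bm)) return(.pkg_cache$bm)
  path <- system.file("extdata", "bm_contact_energies.txt",
                      package = "spiralfold", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) != 20L) stop("corrupted contact-potential file: expected 20 rows")
  parts <- strsplit(trimws(lines), "\\s+")
  labs3 <- vapply(parts, `[[`, character(1), 1L)
  labs1 <- .aa_one[labs3]
  if (anyNA(labs1)) stop("corrupted contact-potential file: unknown residue label")
  m <- matrix(NA_real_, 20L, 20L, dimnames = list(unname(labs1), unname(labs1)))
  for (r in seq_len(20L)) {
    vals <- as.numeric(parts[[r]][-1L])
    if (length(vals) != r)
      stop("corrupted contact-potential file: row ", labs3[r],
           " has ", length(vals), " values, expected ", r)
    m[r, seq_len(r)] <- vals
    m[seq_len(r), r] <- vals
  }
  .pkg_cache$bm <- m
  m
}

#' The Berrera et al. 20x20 contact-potential matrix
#'
#' Symmetric matrix of empirical pairwise contact energies, loaded from the
#' lower-triangular data file shipped with the package and mirrored. Row and
#' column names are one-letter residue codes.
#'
#' @return A 20 x 20 numeric matrix.
#' @export
bm_matrix <- function() .bm_load()

#' Look up a contact-potential entry
#'
#' @param a,b Residues as one-letter or three-letter codes (case
#'   insensitive).
#' @return The symmetric contact energy for the pair.
#' @examples
#' bm_matrix_lookup("C", "C")      # -3.477
#' bm_matrix_lookup("Gly", "GLY")  # 0.219
#' @export
bm_matrix_lookup <- function(a, b) {
  norm1 <- function(r) {
    r <- toupper(r)
    if (nchar(r) == 3L) r <- unname(.aa_one[r])
    if (is.na(r) || !(r %in% rownames(.bm_load())))
      stop("unknown residue: ", r)
    r
  }
  .bm_load()[norm1(a), norm1(b)]
}

#' Nonconsecutive lattice contacts of a conformation
#'
#' Returns all residue index pairs (i, j) with j > i + 1 whose coordinates
#' are at unit lattice distance (squared Euclidean distance 2). Found by
#' probing the 12 lattice neighbours of every residue against the occupancy
#' index, O(n).
#'
#' @param conf An [conformation()] object (or an n x 3 coordinate matrix).
#' @return Integer matrix with columns `i`, `j` (zero rows if no contacts),
#'   ordered by `i` then `j`.
#' @export
contact_pairs <- function(conf) {
  coords <- if (inherits(conf, "fcc_conformation")) conf$coords
            else .as_coord_matrix(conf)
  .contact_pairs(coords, .occ_build(coords))
}

.contact_pairs <- function(coords, occ) {
  n <- nrow(coords)
  if (n < 3L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  nb <- coords[rep(seq_len(n), each = 12L), , drop = FALSE] +
    .fcc_basis[rep(1:12, n), , drop = FALSE]
  j <- .occ_index(occ, .nkey(nb))
  i <- rep(seq_len(n), each = 12L)
  keep <- !is.na(j) & j > i + 1L
  i <- i[keep]
  j <- j[keep]
  ord <- order(i, j)
  cbind(i = i[ord], j = j[ord])
}

# logical H mask from an H/P string
.hp_mask <- function(hpseq) {
  letters_vec <- strsplit(toupper(hpseq), "")[[1]]
  if (!all(letters_vec %in% c("H", "P")))
    stop("HP sequence must use the alphabet {H, P}")
  letters_vec == "H"
}

#' HP contact energy of a conformation
#'
#' Minus the number of nonconsecutive H-H lattice contacts: each pair of
#' hydrophobic residues at unit lattice distance with |i - j| > 1
#' contributes -1; all other contacts contribute 0. Always <= 0.
#'
#' @param conf An [conformation()] object.
#' @param hp Optional H/P string of the same length. When `NULL`, the
#'   conformation's sequence is used: taken verbatim if it is already over
#'   `{H, P}`, otherwise classified via [classify_hp()].
#' @return Integer energy (<= 0).
#' @examples
#' conf <- conformation("HPPH", rbind(c(0,0,0), c(1,1,0), c(2,0,0), c(1,-1,0)))
#' hp_energy(conf)  # -1
#' @export
hp_energy <- function(conf, hp = NULL) {
  stopifnot(inherits(conf, "fcc_conformation"))
  if (is.null(hp)) {
    hp <- if (grepl("^[HPhp]+$", conf$sequence)) conf$sequence
          else classify_hp(conf$sequence)
  }
  if (nchar(hp) != nrow(conf$coords))
    stop("HP sequence length does not match the conformation")
  .hp_energy(conf$coords, .occ_build(conf$coords), .hp_mask(hp))
}

.hp_energy <- function(coords, occ, is_h) {
  pr <- .contact_pairs(coords, occ)
  if (nrow(pr) == 0L) return(0L)
  -sum(is_h[pr[, 1]] & is_h[pr[, 2]])
}

#' Contact-potential (BM) energy of a conformation
#'
#' Sum of the Berrera et al. matrix entries over all nonconsecutive residue
#' pairs at unit lattice distance. Sign-free: entries may be positive.
#'
#' @param conf An [conformation()] object whose sequence uses the 20
#'   standard one-letter codes.
#' @param seq Optional amino-acid string overriding the conformation's
#'   sequence (same length).
#' @return Numeric energy in matrix units.
#' @examples
#' conf <- conformation("KGGK", rbind(c(0,0,0), c(1,1,0), c(2,0,0), c(1,-1,0)))
#' bm_energy(conf)  # 1.339 (terminal Lys-Lys contact)
#' @export
bm_energy <- function(conf, seq = NULL) {
  stopifnot(inherits(conf, "fcc_conformation"))
  if (is.null(seq)) seq <- conf$sequence
  if (nchar(seq) != nrow(conf$coords))
    stop("sequence length does not match the conformation")
  .bm_energy(conf$coords, .occ_build(conf$coords), .aa_index(seq))
}

# residue letters -> row indices of the BM matrix
.aa_index <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], rownames(.bm_load()))
  if (anyNA(idx))
    stop("unknown residue letter(s) for the contact-potential model")
  idx
}

.bm_energy <- function(coords, occ, aa_idx) {
  pr <- .contact_pairs(coords, occ)
  if (nrow(pr) == 0L) return(0)
  m <- .bm_load()
  sum(m[cbind(aa_idx[pr[, 1]], aa_idx[pr[, 2]])])
}
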