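# FCC lattice geometry: 12 basis vectors, neighbourhoods, self-avoiding walks
# and the absolute A..L move-string encoding.

# The 12 FCC basis vectors in fixed A..L order. Each has two nonzero
# components (+-1), squared length 2, and the set is closed under negation
# (A<->J, B<->K, C<->L, D<->G, E<->H, F<->I).
.fcc_basis <- matrix(
  c( 1,  1,  0,   # A
     0,  1,  1,   # B
     1,  0,  1,   # C
    -1,  1,  0,   # D
     0, -1,  1,   # E
    -1,  0,  1,   # F
     1, -1,  0,   # G
     0,  1, -1,   # H
     1,  0, -1,   # I
    -1, -1,  0,   # J
     0, -1, -1,   # K
    -1,  0, -1),  # L
  ncol = 3L, byrow = TRUE,
  dimnames = list(LETTERS[1:12], c("x", "y", "z"))
)
storage.mode(.fcc_basis) <- "integer"

.fcc_basis_keys <- paste(.fcc_basis[, 1], .fcc_basis[, 2], .fcc_basis[, 3])

# string key "x y z" for an n x 3 coordinate matrix (vectorised)
.pt_key <- function(m) paste(m[, 1], m[, 2], m[, 3])

.pt_key1 <- function(p) paste(p[1], p[2], p[3])

.as_coord_matrix <- function(coords) {
  if (is.null(dim(coords))) {
    if (length(coords) %% 3L != 0L)
      stop("coordinates must be an n x 3 matrix or a length-3 multiple vector")
    coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinates must have 3 columns (x, y, z)")
  if (any(coords != round(coords))) stop("lattice coordinates must be integers")
  storage.mode(coords) <- "integer"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' The 12 FCC basis vectors
#'
#' Returns the twelve displacement vectors that connect a face-centred-cubic
#' lattice point to its unit-distance neighbours, in the fixed order
#' `A`..`L` used throughout the package for absolute move strings. Each
#' vector has exactly two nonzero components, each +-1, so its squared
#' Euclidean length is 2; the set is closed under negation (`A`/`J`,
#' `B`/`K`, `C`/`L`, `D`/`G`, `E`/`H`, `F`/`I` are opposite pairs).
#'
#' @return An integer 12 x 3 matrix with row names `A`..`L` and column
#'   names `x`, `y`, `z`.
#' @examples
#' fcc_basis_vectors()["A", ]   # (1, 1, 0)
#' @export
fcc_basis_vectors <- function() .fcc_basis

#' Unit-lattice neighbours of an FCC point
#'
#' @param p Integer vector of length 3, a lattice point.
#' @return Integer 12 x 3 matrix: `p` plus each basis vector, in `A`..`L`
#'   order (row names give the move letter).
#' @examples
#' fcc_neighbors(c(0, 0, 0))
#' @export
fcc_neighbors <- function(p) {
  p <- as.integer(p)
  if (length(p) != 3L) stop("p must be a length-3 integer lattice point")
  m <- .fcc_basis
  m[, 1] <- m[, 1] + p[1]
  m[, 2] <- m[, 2] + p[2]
  m[, 3] <- m[, 3] + p[3]
  m
}

#' Test whether a coordinate list is a valid self-avoiding walk
#'
#' A valid walk visits pairwise-distinct lattice points and every
#' consecutive displacement is one of the 12 FCC basis vectors.
#'
#' @param coords An n x 3 integer matrix (or an `fcc_conformation`, whose
#'   coordinates are used), n >= 1.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_self_avoiding_walk(rbind(c(0, 0, 0), c(1, 1, 0)))   # TRUE
#' is_self_avoiding_walk(rbind(c(0, 0, 0), c(2, 0, 0)))   # FALSE: not a basis step
#' @export
is_self_avoiding_walk <- function(coords) {
  if (inherits(coords, "fcc_conformation")) coords <- coords$coords
  coords <- try(.as_coord_matrix(coords), silent = TRUE)
  if (inherits(coords, "try-error")) return(FALSE)
  n <- nrow(coords)
  if (n < 1L) return(FALSE)
  if (anyDuplicated(.pt_key(coords)) > 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  d <- coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE]
  all(.pt_key(d) %in% .fcc_basis_keys)
}

#' Random self-avoiding walk on the FCC lattice
#'
#' Grows a walk from the origin one residue at a time, choosing uniformly at
#' random among the currently unoccupied basis-vector neighbours of the last
#' point. A dead end (all 12 neighbours occupied) triggers a full restart of
#' the walk, not backtracking; after `max_attempts` restarts an error is
#' raised.
#'
#' @param n Number of residues (walk length), n >= 1.
#' @param seed Optional integer seed; when given the walk is a deterministic
#'   function of `(n, seed)`. When `NULL` the current RNG stream is used.
#' @param max_attempts Maximum number of full restarts before giving up.
#' @return An n x 3 integer coordinate matrix starting at `(0, 0, 0)`.
#' @examples
#' w <- random_saw(50, seed = 1)
#' is_self_avoiding_walk(w)
#' @export
random_saw <- function(n, seed = NULL, max_attempts = 1000L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) return(.as_coord_matrix(c(0L, 0L, 0L)))
  for (attempt in seq_len(max_attempts)) {
    coords <- matrix(0L, nrow = n, ncol = 3L)
    keys <- numeric(n)
    keys[1] <- .nkey1(c(0L, 0L, 0L))
    ok <- TRUE
    for (i in 2:n) {
      nb <- fcc_neighbors(coords[i - 1L, ])
      nbk <- .nkey(nb)
      free <- is.na(match(nbk, keys[seq_len(i - 1L)]))
      if (!any(free)) { ok <- FALSE; break }
      pick <- which(free)[sample.int(sum(free), 1L)]
      coords[i, ] <- nb[pick, ]
      keys[i] <- nbk[pick]
    }
    if (ok) {
      dimnames(coords) <- list(NULL, c("x", "y", "z"))
      return(coords)
    }
  }
  stop("random_saw: failed to generate a self-avoiding walk of length ", n,
       " after ", max_attempts, " restarts")
}

#' Encode a walk as an absolute move string
#'
#' Maps each consecutive displacement of a self-avoiding walk to its basis
#' vector letter `A`..`L`; the encoding is translation invariant.
#'
#' @param coords An n x 3 integer matrix or an `fcc_conformation`.
#' @return A single string of length n - 1 (empty string for n = 1).
#' @examples
#' encode_absolute(rbind(c(0, 0, 0), c(1, 1, 0)))  # "A"
#' @export
encode_absolute <- function(coords) {
  if (inherits(coords, "fcc_conformation")) coords <- coords$coords
  coords <- .as_coord_matrix(coords)
  n <- nrow(coords)
  if (n == 1L) return("")
  d <- coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE]
  idx <- match(.pt_key(d), .fcc_basis_keys)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("displacement at step ", bad, " is not an FCC basis vector")
  }
  paste(LETTERS[idx], collapse = "")
}

#' Decode an absolute move string into coordinates
#'
#' Inverse of [encode_absolute()]. Decoding does not check self-avoidance;
#' validate with [is_self_avoiding_walk()] if required.
#'
#' @param moves String over the alphabet `A`..`L` (may be empty).
#' @param origin Integer length-3 starting point, default the origin.
#' @return An (nchar(moves) + 1) x 3 integer coordinate matrix.
#' @examples
#' decode_absolute("AJ")  # returns to the origin; fails the SAW check
#' @export
decode_absolute <- function(moves, origin = c(0L, 0L, 0L)) {
  stopifnot(is.character(moves), length(moves) == 1L)
  origin <- as.integer(origin)
  if (length(origin) != 3L) stop("origin must be a length-3 lattice point")
  if (nchar(moves) == 0L) return(.as_coord_matrix(origin))
  letters_vec <- strsplit(moves, "", fixed = TRUE)[[1]]
  idx <- match(letters_vec, LETTERS[1:12])
  if (anyNA(idx)) {
    stop("unknown move letter: ", letters_vec[which(is.na(idx))[1]],
         " (alphabet is A..L)")
  }
  steps <- .fcc_basis[idx, , drop = FALSE]
  cum <- apply(steps, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = 3L)  # single step
  .as_coord_matrix(rbind(origin, sweep(cum, 2L, origin, "+")))
}

# --- occupancy index ------------------------------------------------------
# A conformation's occupancy is a per-residue numeric point key; membership
# queries go through vectorised match(). Keys pack (x, y, z) into a single
# double, exact for coordinates in (-2048, 2048) -- far beyond any chain the
# lattice walk can reach.

.nkey <- function(m) {
  ((as.numeric(m[, 1]) + 2048) * 4096 + (m[, 2] + 2048)) * 4096 +
    (m[, 3] + 2048)
}

.nkey1 <- function(p) {
  ((as.numeric(p[1]) + 2048) * 4096 + (p[2] + 2048)) * 4096 + (p[3] + 2048)
}

.occ_build <- function(coords) {
  occ <- new.env(parent = emptyenv())
  occ$keys <- .nkey(coords)
  occ
}

# residue indices occupying the given keys (NA where free)
.occ_index <- function(occ, keys) match(keys, occ$keys)

.occ_free <- function(occ, keys) is.na(match(keys, occ$keys))

# common free neighbours of coords[i-1,] and coords[i+1,], in the basis-vector
# order around coords[i-1,]; returns m x 3 matrix (m may be 0)
.cfn <- function(coords, i, occ) {
  a <- fcc_neighbors(coords[i - 1L, ])
  ka <- .nkey(a)
  common <- ka %in% .nkey(fcc_neighbors(coords[i + 1L, ]))
  if (!any(common)) return(a[0L, , drop = FALSE])
  ka <- ka[common]
  a <- a[common, , drop = FALSE]
  a[is.na(match(ka, occ$keys)), , drop = FALSE]
}

#' Common free neighbours of a residue's two chain neighbours
#'
#' For an interior residue i (1-based, 2 <= i <= n - 1), returns the
#' unoccupied lattice points that are unit neighbours of both residue i - 1
#' and residue i + 1: the legal targets of a diagonal (corner-flip) move of
#' residue i. The residue's current position is occupied and therefore never
#' returned. Points are ordered by the basis-vector order around residue
#' i - 1 (ties in move selection break on this order).
#'
#' @param conf An [conformation()] object.
#' @param i Interior residue index, 1-based.
#' @return An m x 3 integer matrix, possibly with zero rows.
#' @export
common_free_neighbors <- function(conf, i) {
  stopifnot(inherits(conf, "fcc_conformation"))
  n <- nrow(conf$coords)
  i <- as.integer(i)
  if (length(i) != 1L || i < 2L || i > n - 1L)
    stop("i must be an interior residue index (2 <= i <= n - 1)")
  .cfn(conf$coords, i, .occ_build(conf$coords))
}
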