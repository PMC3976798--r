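# Conformation perturbation operators: the diagonal (corner-flip) move used
# by spiral search, and a pull-move random walk used to escape premature
# hydrophobic cores.

#' Diagonal (corner-flip) move
#'
#' Relocates interior residue `i` to `target`, an unoccupied lattice point
#' that is a unit neighbour of both residue `i - 1` and residue `i + 1`.
#' All other residues keep their positions; the result is again a valid
#' self-avoiding walk. The input conformation is not modified.
#'
#' @param conf An [conformation()] object.
#' @param i Interior residue index (1-based).
#' @param target Length-3 integer lattice point; must be a common free
#'   neighbour of the two flanking residues, otherwise an error is raised.
#' @return A new `fcc_conformation`.
#' @examples
#' conf <- conformation("HPPH", rbind(c(0,0,0), c(1,1,0), c(2,0,0), c(1,-1,0)))
#' diagonal_move(conf, 2, c(1, 0, 1))
#' @export
diagonal_move <- function(conf, i, target) {
  stopifnot(inherits(conf, "fcc_conformation"))
  target <- as.integer(target)
  if (length(target) != 3L) stop("target must be a length-3 lattice point")
  legal <- common_free_neighbors(conf, i)  # validates interior i
  if (!(.pt_key1(target) %in% .pt_key(legal)))
    stop("target is occupied or not a common neighbour of residues ",
         i - 1L, " and ", i + 1L)
  coords <- conf$coords
  coords[i, ] <- target
  conformation(conf$sequence, coords, validate = FALSE)
}

# --- pull move ------------------------------------------------------------
# Generalised pull move on the 12-neighbour FCC lattice. For a tail-pull at
# residue i: pick a free point q adjacent to both coords[i] and
# coords[i+1]; relocate i to q, then shift residues i-1, i-2, ... into the
# positions vacated above them until the chain reconnects. The head-pull is
# the mirror image. By construction every accepted pull yields a valid SAW.

# One pull application; updates occ in place and returns the new coords.
# dir = -1: tail-pull (bond to i+1 kept, residues i-1, i-2, ... shifted);
# dir = +1: head-pull (mirror image). q must be free and adjacent to both
# coords[i] and coords[i - dir].
.pull_apply <- function(coords, occ, i, dir, q) {
  n <- nrow(coords)
  old <- coords
  coords[i, ] <- q
  k <- i + dir
  while (k >= 1L && k <= n) {
    # chain reconnects when old position of k bonds to the just-placed
    # new position of residue k - dir
    delta <- old[k, ] - coords[k - dir, ]
    if (.pt_key1(delta) %in% .fcc_basis_keys) break
    coords[k, ] <- old[k - dir, ]  # drag into the vacated position
    k <- k + dir
  }
  last_moved <- k - dir
  moved <- if (dir == -1L) seq.int(last_moved, i) else seq.int(i, last_moved)
  occ$keys[moved] <- .nkey(coords[moved, , drop = FALSE])
  coords
}

# candidate q points for a pull at residue i in direction dir:
# free points adjacent to both coords[i] and the anchor coords[i - dir'],
# where the bond kept is towards i+1 (tail-pull) or i-1 (head-pull)
.pull_candidates <- function(coords, occ, i, dir) {
  n <- nrow(coords)
  anchor <- i - dir  # tail-pull (dir=-1): anchor i+1; head-pull: anchor i-1
  if (anchor < 1L || anchor > n) return(coords[0L, , drop = FALSE])
  a <- fcc_neighbors(coords[i, ])
  ka <- .nkey(a)
  common <- ka %in% .nkey(fcc_neighbors(coords[anchor, ]))
  if (!any(common)) return(coords[0L, , drop = FALSE])
  a <- a[common, , drop = FALSE]
  a[.occ_free(occ, ka[common]), , drop = FALSE]
}

# one random pull-move step on (coords, occ); returns new coords or NULL
.pull_step <- function(coords, occ, max_proposals = 30L) {
  n <- nrow(coords)
  if (n < 2L) return(NULL)
  for (t in seq_len(max_proposals)) {
    i <- sample.int(n, 1L)
    dir <- if (sample.int(2L, 1L) == 1L) -1L else 1L
    cand <- .pull_candidates(coords, occ, i, dir)
    if (nrow(cand) == 0L) next
    q <- cand[sample.int(nrow(cand), 1L), ]
    return(.pull_apply(coords, occ, i, dir, q))
  }
  NULL
}

#' Pull-move random walk
#'
#' Applies a sequence of randomly chosen pull moves: residue `i` is
#' relocated to a free point adjacent to both its own position and one of
#' its chain neighbours, and the residues on the far side are dragged into
#' the vacated positions until the chain reconnects. Every intermediate
#' conformation is a valid self-avoiding walk. Pull moves are accepted
#' unconditionally (the walk is an escape mechanism, not an optimiser); a
#' step with no feasible proposal is skipped and still counted.
#'
#' @param conf An [conformation()] object.
#' @param steps Number of pull-move attempts, >= 0.
#' @param seed Optional integer seed; the walk is deterministic per
#'   `(conf, steps, seed)`.
#' @param max_proposals Random (residue, direction) proposals tried per
#'   step before the step is skipped.
#' @return A new `fcc_conformation`.
#' @export
random_walk <- function(conf, steps = 20L, seed = NULL, max_proposals = 30L) {
  stopifnot(inherits(conf, "fcc_conformation"))
  steps <- as.integer(steps)
  if (steps < 0L) stop("steps must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  coords <- conf$coords
  occ <- .occ_build(coords)
  for (s in seq_len(steps)) {
    res <- .pull_step(coords, occ, max_proposals)
    if (!is.null(res)) coords <- res
  }
  conformation(conf$sequence, coords, validate = FALSE)
}
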