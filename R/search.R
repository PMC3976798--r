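# Core-directed tabu local search ("spiral search") on the FCC lattice.
# The HP-guided variant pulls hydrophobic residues towards the hydrophobic
# core centre (HCC) with diagonal moves and gives polar residues occasional
# random diagonal moves; the contact-matrix-guided (BM) variant treats all
# residues alike and pulls them towards the centroid of the whole chain.
# Stagnation is handled by pull-move random walks and relay-restarts from
# the improving-solution list.

#' Core centre of a residue subset
#'
#' Componentwise arithmetic mean of the coordinates of the given residues:
#' the hydrophobic core centre (HCC) when the subset holds the H residues,
#' the chain centroid (CC) when it holds all residues.
#'
#' @param conf An [conformation()] object.
#' @param subset Integer vector of 1-based residue indices, nonempty.
#' @return Numeric length-3 vector (x, y, z), in lattice units.
#' @export
core_centre <- function(conf, subset) {
  stopifnot(inherits(conf, "fcc_conformation"))
  subset <- as.integer(subset)
  if (length(subset) == 0L)
    stop("core centre undefined for an empty residue subset")
  if (any(subset < 1L | subset > nrow(conf$coords)))
    stop("subset indices out of range")
  colMeans(conf$coords[subset, , drop = FALSE])
}

#' Euclidean distance from a lattice point to a core centre
#'
#' @param p Length-3 point (integer lattice point or real).
#' @param centre Length-3 numeric centre, e.g. from [core_centre()].
#' @return Nonnegative real distance.
#' @export
distance_to_centre <- function(p, centre) {
  sqrt(sum((as.numeric(p) - as.numeric(centre))^2))
}

#' Tabu tenure from a residue count
#'
#' `floor(10 + count / 10)`: the number of iterations a just-moved residue
#' stays unselectable. The HP-guided search uses the hydrophobic residue
#' count; the matrix-guided variant applies the same formula to the total
#' residue count (its tabu list spans all residues).
#'
#' @param count Nonnegative residue count.
#' @return Integer tenure.
#' @examples
#' tabu_tenure(0)    # 10
#' tabu_tenure(48)   # 14
#' tabu_tenure(105)  # 20
#' @export
tabu_tenure <- function(count) {
  count <- as.integer(count)
  if (any(count < 0L)) stop("count must be >= 0")
  as.integer(floor(10 + count / 10))
}

#' Create a spiral-search state
#'
#' Builds the mutable search state used by the move-selection operators and
#' by [spiral_search()]: current and best conformations, per-residue tabu
#' expiries, the improving-solution list and stagnation counters.
#'
#' @param conf Starting [conformation()].
#' @param guidance `"HP"` (hydrophobic-core directed; scores with the HP
#'   contact energy) or `"BM"` (chain-centroid directed; scores with the
#'   Berrera et al. contact potential).
#' @param sequence_type How to read the sequence letters: `"aa"` (standard
#'   amino acids), `"hp"` (an H/P string), or `"auto"` (default): a
#'   sequence over `{H, P}` is taken as an H/P string under HP guidance and
#'   as His/Pro under BM guidance.
#' @return An environment of class `search_state`.
#' @export
search_state <- function(conf, guidance = c("HP", "BM"),
                         sequence_type = c("auto", "aa", "hp")) {
  stopifnot(inherits(conf, "fcc_conformation"))
  guidance <- match.arg(guidance)
  sequence_type <- match.arg(sequence_type)
  seq <- conf$sequence
  n <- nrow(conf$coords)
  if (sequence_type == "auto") {
    if (grepl("^[HP]+$", seq)) {
      if (guidance == "HP") {
        sequence_type <- "hp"
      } else {
        stop("sequence uses only the letters H and P: the contact-matrix ",
             "guidance needs an amino-acid reading; pass sequence_type = ",
             "\"aa\" to interpret them as His/Pro")
      }
    } else {
      sequence_type <- "aa"
    }
  }
  if (guidance == "BM" && sequence_type == "hp")
    stop("the contact-matrix guidance needs a 20-letter amino-acid sequence")

  st <- new.env(parent = emptyenv())
  st$sequence <- seq
  st$sequence_type <- sequence_type
  st$n <- n
  st$guidance <- guidance
  st$hp <- if (sequence_type == "hp") seq else classify_hp(seq)
  st$is_h <- .hp_mask(st$hp)
  st$aa_idx <- if (sequence_type == "aa") .aa_index(seq) else NULL
  st$coords <- conf$coords
  st$occ <- .occ_build(conf$coords)
  if (guidance == "HP") {
    st$centre_subset <- which(st$is_h)
    st$tenure <- tabu_tenure(sum(st$is_h))
  } else {
    st$centre_subset <- seq_len(n)
    st$tenure <- tabu_tenure(n)
  }
  st$tabu <- rep(0L, n)          # expiry iteration per residue
  st$iteration <- 0L
  e0 <- .state_energy(st)
  st$energy <- e0
  st$best_coords <- conf$coords
  st$best_energy <- e0
  st$improving <- list(list(coords = conf$coords, energy = e0))
  st$improvement_log <- list(list(iteration = 0L, energy = e0))
  st$non_improving <- 0L
  st$walks_since_improve <- 0L
  st$n_walks <- 0L
  st$n_restarts <- 0L
  st$trace <- NULL
  class(st) <- "search_state"
  st
}

.state_energy <- function(st) {
  if (st$guidance == "HP") .hp_energy(st$coords, st$occ, st$is_h)
  else .bm_energy(st$coords, st$occ, st$aa_idx)
}

# record an applied perturbation: update counters, best and improving list
.state_record <- function(st, event, residue = NA_integer_) {
  e <- .state_energy(st)
  st$energy <- e
  if (e < st$best_energy) {
    st$best_energy <- e
    st$best_coords <- st$coords
    st$improving[[length(st$improving) + 1L]] <- list(coords = st$coords, energy = e)
    st$improvement_log[[length(st$improvement_log) + 1L]] <-
      list(iteration = st$iteration, energy = e)
    st$non_improving <- 0L
    st$walks_since_improve <- 0L
  } else {
    st$non_improving <- st$non_improving + 1L
  }
  if (!is.null(st$trace))
    st$trace[[length(st$trace) + 1L]] <-
      list(iteration = st$iteration, event = event, residue = residue,
           energy = e, best_energy = st$best_energy)
  invisible(e)
}

# apply a diagonal move to residue i (no legality re-check: callers pass
# points from .cfn); counts one iteration
.state_apply <- function(st, i, target, update_tabu, event) {
  st$coords[i, ] <- target
  st$occ$keys[i] <- .nkey1(target)
  st$iteration <- st$iteration + 1L
  if (update_tabu) st$tabu[i] <- st$iteration + st$tenure
  .state_record(st, event, residue = i)
}

# shared candidate scan for the two core-directed selections: over the given
# movable residues, find each residue's closest admissible diagonal target
# (strictly closer to the centre than its current position) and return the
# globally best candidate. Ties break on lowest residue index, then on the
# basis-vector order of targets.
.select_core_move <- function(st, residues) {
  if (length(st$centre_subset) == 0L || length(residues) == 0L) return(NULL)
  coords <- st$coords
  # Distances to the centre (a coordinate mean with denominator m) are
  # compared through m^2 * d^2 = sum((m * p - s)^2) with s the integer
  # coordinate sums: exact integer arithmetic, so the strict-improvement
  # admission and all tie-breaks are reproducible across platforms.
  m <- length(st$centre_subset)
  s <- colSums(coords[st$centre_subset, , drop = FALSE])
  r <- length(residues)
  # neighbours of both flanks for all candidate residues at once
  rep12 <- rep(seq_len(r), each = 12L)
  basis <- .fcc_basis[rep(1:12, r), , drop = FALSE]
  a <- coords[residues - 1L, , drop = FALSE][rep12, , drop = FALSE] + basis
  ka <- .nkey(a)
  kb <- .nkey(coords[residues + 1L, , drop = FALSE][rep12, , drop = FALSE] + basis)
  # membership restricted to the same residue: offset keys by group id
  grp_off <- rep12 * 2^37
  cand <- (ka + grp_off) %in% (kb + grp_off) & is.na(match(ka, st$occ$keys))
  if (!any(cand)) return(NULL)
  idx <- which(cand)
  nd2 <- (m * a[idx, 1] - s[1])^2 + (m * a[idx, 2] - s[2])^2 +
    (m * a[idx, 3] - s[3])^2
  ri <- residues[rep12[idx]]
  cur <- coords[ri, , drop = FALSE]
  od2 <- (m * cur[, 1] - s[1])^2 + (m * cur[, 2] - s[2])^2 +
    (m * cur[, 3] - s[3])^2
  ok <- nd2 < od2                          # strict improvement admission
  if (!any(ok)) return(NULL)
  # rows are ordered by residue then basis vector, so the first minimum
  # realises the tie-break: lowest residue index, then basis order
  j <- which(ok)[which.min(nd2[ok])]
  structure(list(residue = ri[j], target = a[idx[j], ],
                 new_distance = sqrt(nd2[j]) / m,
                 old_distance = sqrt(od2[j]) / m),
            class = "move_candidate")
}

# residues currently selectable: interior, non-tabu, optionally H-only
.movable <- function(st, h_only) {
  if (st$n < 3L) return(integer(0))
  idx <- 2:(st$n - 1L)
  idx <- idx[st$iteration >= st$tabu[idx]]
  if (h_only) idx <- idx[st$is_h[idx]]
  idx
}

#' Select the best hydrophobic diagonal move
#'
#' Scans all non-tabu interior hydrophobic residues; for each, the free
#' common neighbour of its flanks closest to the hydrophobic core centre is
#' admitted if strictly closer than the residue's current position. The
#' candidate with the globally smallest new distance is returned, or `NULL`
#' when no residue has an admissible move (which hands control to the
#' polar-move pass).
#'
#' @param state A [search_state()] with HP guidance.
#' @return A `move_candidate` (fields `residue`, `target`, `new_distance`,
#'   `old_distance`) or `NULL`.
#' @export
select_h_move <- function(state) {
  stopifnot(inherits(state, "search_state"))
  if (state$guidance != "HP") stop("select_h_move() needs HP guidance")
  .select_core_move(state, .movable(state, h_only = TRUE))
}

#' Select the best diagonal move under contact-matrix guidance
#'
#' Same scan as [select_h_move()] but over all non-tabu interior residues,
#' with the centre taken as the centroid of the whole chain.
#'
#' @param state A [search_state()] with BM guidance.
#' @return A `move_candidate` or `NULL`.
#' @export
select_move_bm <- function(state) {
  stopifnot(inherits(state, "search_state"))
  if (state$guidance != "BM") stop("select_move_bm() needs BM guidance")
  .select_core_move(state, .movable(state, h_only = FALSE))
}

#' Polar-move pass
#'
#' Gives every interior polar residue one try, in index order: if the
#' residue has free common neighbours of its flanks, one is chosen
#' uniformly at random and the diagonal move is applied immediately. No
#' core centre, distances or tabu list are involved. Each applied move
#' counts one search iteration.
#'
#' @param state A [search_state()] with HP guidance.
#' @param budget Optional iteration cap; the pass stops once
#'   `state$iteration` reaches it.
#' @return Invisibly, the list of applied `move_candidate`s (empty when no
#'   polar residue had a feasible target).
#' @export
select_p_move <- function(state, budget = Inf) {
  stopifnot(inherits(state, "search_state"))
  if (state$guidance != "HP") stop("select_p_move() needs HP guidance")
  applied <- list()
  if (state$n >= 3L) {
    for (i in (2:(state$n - 1L))[!state$is_h[2:(state$n - 1L)]]) {
      if (state$iteration >= budget) break
      pts <- .cfn(state$coords, i, state$occ)
      if (nrow(pts) == 0L) next
      target <- pts[sample.int(nrow(pts), 1L), ]
      .state_apply(state, i, target, update_tabu = FALSE, event = "P-move")
      applied[[length(applied) + 1L]] <-
        structure(list(residue = i, target = target,
                       new_distance = NA_real_, old_distance = NA_real_),
                  class = "move_candidate")
    }
  }
  invisible(applied)
}

#' Relay-restart from the improving-solution list
#'
#' Replaces the current conformation with one drawn uniformly at random
#' from the improving-solution list, and resets the tabu list and
#' stagnation counters. With an empty improving list (possible only for
#' externally built states) a fresh random self-avoiding walk is used
#' instead.
#'
#' @param state A [search_state()].
#' @return Invisibly, the conformation the search resumes from.
#' @export
relay_restart <- function(state) {
  stopifnot(inherits(state, "search_state"))
  if (length(state$improving) > 0L) {
    pick <- state$improving[[sample.int(length(state$improving), 1L)]]
    state$coords <- pick$coords
  } else {
    state$coords <- random_saw(state$n)
  }
  state$occ <- .occ_build(state$coords)
  state$energy <- .state_energy(state)
  state$tabu <- rep(0L, state$n)
  state$non_improving <- 0L
  state$walks_since_improve <- 0L
  state$n_restarts <- state$n_restarts + 1L
  invisible(conformation(state$sequence, state$coords, validate = FALSE))
}

# in-state pull-move random walk: each accepted pull counts one iteration;
# the conformation is evaluated once at the end of the walk
.state_random_walk <- function(st, steps, budget, max_proposals = 30L) {
  k <- 0L
  while (k < steps && st$iteration < budget) {
    res <- .pull_step(st$coords, st$occ, max_proposals)
    if (!is.null(res)) st$coords <- res
    k <- k + 1L
    st$iteration <- st$iteration + 1L
  }
  st$n_walks <- st$n_walks + 1L
  st$tabu <- rep(0L, st$n)
  before <- st$best_energy
  .state_record(st, "random-walk")
  st$non_improving <- 0L
  if (st$best_energy >= before)
    st$walks_since_improve <- st$walks_since_improve + 1L
  invisible(NULL)
}

#' Tabu spiral search on the FCC lattice
#'
#' Runs the core-directed tabu local search from a random (or given)
#' self-avoiding walk. Under HP guidance the main loop applies the best
#' hydrophobic diagonal move while one exists, then gives each polar
#' residue one random diagonal-move try, and repeats; under BM guidance it
#' repeatedly applies the best centroid-directed move over all residues.
#' Every applied move is scored with the guidance model's energy and
#' best-so-far plus the improving-solution list are maintained. Stagnation
#' (`max_stagnation` applied moves without a new best, or a pass with no
#' applicable move) triggers a pull-move random walk; when `max_walks`
#' consecutive walks fail to improve the best, a relay-restart resumes from
#' a random improving solution.
#'
#' @param sequence Residue string: one-letter amino acids, or an H/P string
#'   (see `sequence_type`).
#' @param guidance `"HP"` or `"BM"`.
#' @param budget Iteration budget: total number of applied perturbations
#'   (diagonal moves and pull-move steps). `budget = 0` just evaluates the
#'   start conformation.
#' @param seed Optional integer seed; the full run is deterministic per
#'   `(sequence, guidance, budget, seed, start)`.
#' @param start Optional starting [conformation()]; default a fresh random
#'   self-avoiding walk.
#' @param sequence_type See [search_state()].
#' @param max_stagnation Applied moves without improvement that trigger a
#'   random walk (default 200).
#' @param max_walks Consecutive unimproving random walks before a
#'   relay-restart (default 2).
#' @param walk_steps Pull-move attempts per random walk (default 20).
#' @param record_trace Keep a per-iteration event log (default `FALSE`;
#'   the log of improving iterations is always kept).
#' @return An object of class `spiral_search`; see [print.spiral_search()].
#' @examples
#' fit <- spiral_search("HPHPPHHPHPPHPHHPPHPH", budget = 200, seed = 1)
#' fit$best_energy
#' @export
spiral_search <- function(sequence = NULL, guidance = c("HP", "BM"), budget = 2000L,
                          seed = NULL, start = NULL,
                          sequence_type = c("auto", "aa", "hp"),
                          max_stagnation = 200L, max_walks = 2L,
                          walk_steps = 20L, record_trace = FALSE) {
  guidance <- match.arg(guidance)
  sequence_type <- match.arg(sequence_type)
  budget <- as.integer(budget)
  if (budget < 0L) stop("budget must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    start <- conformation(toupper(sequence), random_saw(nchar(sequence)),
                          validate = FALSE)
  } else {
    stopifnot(inherits(start, "fcc_conformation"))
    if (!is.null(sequence) && toupper(sequence) != start$sequence)
      stop("sequence does not match the start conformation")
  }
  st <- search_state(start, guidance, sequence_type)
  if (record_trace) st$trace <- list()

  while (st$iteration < budget) {
    moved_any <- FALSE
    if (guidance == "HP") {
      repeat {
        if (st$iteration >= budget || st$non_improving >= max_stagnation) break
        mv <- select_h_move(st)
        if (is.null(mv)) break
        .state_apply(st, mv$residue, mv$target, update_tabu = TRUE,
                     event = "H-move")
        moved_any <- TRUE
      }
      if (st$iteration < budget && st$non_improving < max_stagnation) {
        applied <- select_p_move(st, budget = budget)
        if (length(applied) > 0L) moved_any <- TRUE
      }
    } else {
      repeat {
        if (st$iteration >= budget || st$non_improving >= max_stagnation) break
        mv <- select_move_bm(st)
        if (is.null(mv)) break
        .state_apply(st, mv$residue, mv$target, update_tabu = TRUE,
                     event = "BM-move")
        moved_any <- TRUE
      }
    }
    if (st$iteration >= budget) break
    if (st$non_improving >= max_stagnation || !moved_any) {
      if (st$walks_since_improve >= max_walks) {
        relay_restart(st)
        if (!is.null(st$trace))
          st$trace[[length(st$trace) + 1L]] <-
            list(iteration = st$iteration, event = "relay-restart",
                 residue = NA_integer_, energy = st$energy,
                 best_energy = st$best_energy)
      } else {
        .state_random_walk(st, walk_steps, budget)
      }
    }
  }

  structure(list(
    sequence = st$sequence,
    hp = st$hp,
    guidance = guidance,
    budget = budget,
    iterations = st$iteration,
    best = conformation(st$sequence, st$best_coords, validate = FALSE),
    best_energy = st$best_energy,
    initial_energy = st$improving[[1]]$energy,
    improving = st$improving,
    improvements = do.call(rbind, lapply(st$improvement_log, function(r)
      data.frame(iteration = r$iteration, energy = r$energy))),
    n_walks = st$n_walks,
    n_restarts = st$n_restarts,
    trace = if (is.null(st$trace)) NULL else
      do.call(rbind, lapply(st$trace, as.data.frame)),
    seed = seed
  ), class = "spiral_search")
}

#' @export
print.spiral_search <- function(x, ...) {
  cat("Spiral search (", x$guidance, "-guided tabu local search)\n", sep = "")
  cat("  sequence length:", nchar(x$sequence), "\n")
  cat("  iterations:     ", x$iterations, "of", x$budget, "\n")
  cat("  energy:         ", x$initial_energy, "->", x$best_energy, "\n")
  cat("  random walks:", x$n_walks, " relay-restarts:", x$n_restarts, "\n")
  invisible(x)
}

#' @export
summary.spiral_search <- function(object, ...) {
  cat("Spiral search summary\n")
  print(object)
  cat("  improving solutions:", length(object$improving), "\n")
  if (nrow(object$improvements) > 1)
    cat("  last improvement at iteration",
        object$improvements$iteration[nrow(object$improvements)], "\n")
  invisible(object)
}

#' Plot the best-so-far energy profile of a spiral search run
#'
#' @param x A `spiral_search` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spiral_search <- function(x, ...) {
  imp <- x$improvements
  graphics::plot(c(imp$iteration, x$iterations), c(imp$energy, x$best_energy),
                 type = "s", xlab = "iteration (applied moves)",
                 ylab = paste(x$guidance, "energy (best so far)"), ...)
  invisible(x)
}
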