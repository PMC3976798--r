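# Multipoint parallel spiral search: rounds of independent workers running
# HP- or BM-guided spiral search from different starting points, with
# merge, deduplication and reselection of the improving solutions at round
# boundaries. Workers are pure functions of (start, guidance, budget, seed),
# so results are identical whatever the execution order.

.canonical_mixes <- list(
  PSSB4H0 = c(bm = 4L, hp = 0L),
  PSSB3H1 = c(bm = 3L, hp = 1L),
  PSSB2H2 = c(bm = 2L, hp = 2L),
  PSSB1H3 = c(bm = 1L, hp = 3L),
  PSSB0H4 = c(bm = 0L, hp = 4L)
)

#' Portfolio mixes of guidance models across workers
#'
#' The canonical four-worker portfolios `PSSB4H0` .. `PSSB0H4` mix `x`
#' workers guided by the Berrera contact matrix with `y` workers guided by
#' the HP model. Arbitrary mixes can be given as counts.
#'
#' @param mix A label (`"PSSB1H3"` or the short form `"B1H3"`), or a named
#'   vector/list with elements `bm` and `hp`.
#' @return An object of class `portfolio_mix` with fields `label`,
#'   `bm_workers`, `hp_workers`.
#' @examples
#' portfolio_mix("B1H3")
#' portfolio_mix(c(bm = 0, hp = 2))
#' @export
portfolio_mix <- function(mix) {
  if (inherits(mix, "portfolio_mix")) return(mix)
  if (is.character(mix)) {
    lab <- toupper(mix)
    if (!startsWith(lab, "PSS")) lab <- paste0("PSS", lab)
    m <- regmatches(lab, regexec("^PSSB([0-9]+)H([0-9]+)$", lab))[[1]]
    if (length(m) != 3L) stop("unrecognised portfolio mix label: ", mix)
    counts <- c(bm = as.integer(m[2]), hp = as.integer(m[3]))
  } else {
    counts <- c(bm = as.integer(mix[["bm"]]), hp = as.integer(mix[["hp"]]))
    lab <- sprintf("PSSB%dH%d", counts["bm"], counts["hp"])
  }
  if (any(is.na(counts)) || any(counts < 0L) || sum(counts) < 1L)
    stop("a portfolio mix needs at least one worker")
  structure(list(label = lab, bm_workers = unname(counts["bm"]),
                 hp_workers = unname(counts["hp"])),
            class = "portfolio_mix")
}

#' @export
print.portfolio_mix <- function(x, ...) {
  cat("Portfolio mix ", x$label, ": ", x$bm_workers, " BM-guided + ",
      x$hp_workers, " HP-guided worker(s)\n", sep = "")
  invisible(x)
}

# --- canonical keys and pools ---------------------------------------------

# the 48 signed permutation matrices (lattice point-group of the FCC lattice)
.fcc_symmetries <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- vector("list", 48L)
  k <- 0L
  for (p in perms) for (s in seq_len(nrow(signs))) {
    k <- k + 1L
    out[[k]] <- list(perm = p, sign = as.integer(signs[s, ]))
  }
  out
})

#' Canonical key of a conformation
#'
#' The default key is the absolute move string, which already identifies
#' walks up to lattice translation. With `symmetry = TRUE` the key is the
#' lexicographic minimum of the move string over the 48 point-group
#' symmetries of the FCC lattice (rotations and reflections), collapsing
#' symmetry-related duplicates as well.
#'
#' @param conf An [conformation()] object.
#' @param symmetry Canonicalise over the 48 lattice symmetries (default
#'   `FALSE`).
#' @return A single string.
#' @export
canonical_key <- function(conf, symmetry = FALSE) {
  stopifnot(inherits(conf, "fcc_conformation"))
  if (!symmetry) return(encode_absolute(conf$coords))
  keys <- vapply(.fcc_symmetries, function(tr) {
    m <- conf$coords[, tr$perm, drop = FALSE]
    m[, 1] <- m[, 1] * tr$sign[1]
    m[, 2] <- m[, 2] * tr$sign[2]
    m[, 3] <- m[, 3] * tr$sign[3]
    encode_absolute(m)
  }, character(1))
  min(keys)
}

# score a conformation under the pool's evaluation model
.score_conf <- function(conf, model) {
  if (model == "HP") hp_energy(conf) else bm_energy(conf)
}

#' Merge worker solution lists into a deduplicated, rescored pool
#'
#' Takes the union of the given solution lists, removes duplicates
#' (identical canonical keys; the first occurrence is kept) and scores
#' every member under the pool's evaluation model.
#'
#' @param solution_lists A list of lists of [conformation()] objects (a
#'   single flat list of conformations is also accepted).
#' @param evaluation_model `"HP"` or `"BM"`. Mixed-model portfolios score
#'   pools with the contact-matrix (BM) energy.
#' @param symmetry Use symmetry-canonical keys (see [canonical_key()]).
#' @return An object of class `solution_pool`: list with `members` (each a
#'   list with `conf`, `score`, `key`) and `evaluation_model`.
#' @export
merge_and_dedupe <- function(solution_lists, evaluation_model = c("BM", "HP"),
                             symmetry = FALSE) {
  evaluation_model <- match.arg(evaluation_model)
  if (length(solution_lists) > 0L && inherits(solution_lists[[1]], "fcc_conformation"))
    solution_lists <- list(solution_lists)
  members <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (lst in solution_lists) {
    for (conf in lst) {
      stopifnot(inherits(conf, "fcc_conformation"))
      key <- canonical_key(conf, symmetry = symmetry)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      members[[length(members) + 1L]] <-
        list(conf = conf, score = .score_conf(conf, evaluation_model), key = key)
    }
  }
  structure(list(members = members, evaluation_model = evaluation_model,
                 symmetry = symmetry),
            class = "solution_pool")
}

#' @export
print.solution_pool <- function(x, ...) {
  sc <- vapply(x$members, `[[`, numeric(1), "score")
  cat("Solution pool:", length(x$members), "distinct conformations,",
      x$evaluation_model, "scores",
      if (length(sc)) paste0("[", min(sc), ", ", max(sc), "]") else "", "\n")
  invisible(x)
}

#' Select the most promising distinct solutions from a pool
#'
#' Returns the `k` lowest-score members (ties broken by insertion order).
#' When the pool holds fewer than `k` members, the selection is topped up
#' with fresh random self-avoiding walks of the pool's sequence.
#'
#' @param pool A `solution_pool` from [merge_and_dedupe()].
#' @param k Number of solutions to select, >= 1.
#' @param sequence Sequence used for top-up walks when the pool is empty
#'   (otherwise taken from the pool members).
#' @return A list of `k` conformations.
#' @export
select_distinct_subset <- function(pool, k, sequence = NULL) {
  stopifnot(inherits(pool, "solution_pool"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sc <- vapply(pool$members, `[[`, numeric(1), "score")
  take <- order(sc)[seq_len(min(k, length(sc)))]   # stable: insertion order ties
  out <- lapply(pool$members[take], `[[`, "conf")
  if (length(out) < k) {
    if (is.null(sequence)) {
      if (length(out) == 0L)
        stop("cannot top up an empty pool without a sequence")
      sequence <- out[[1]]$sequence
    }
    for (j in seq_len(k - length(out)))
      out[[length(out) + 1L]] <-
        conformation(sequence, random_saw(nchar(sequence)), validate = FALSE)
  }
  out
}

# run one worker start with an isolated RNG stream, preserving the caller's
.run_worker <- function(start, guidance, budget, seed, ...) {
  keep <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(keep)) assign(".Random.seed", keep, globalenv()))
  spiral_search(guidance = guidance, budget = budget, seed = seed,
                start = start, ...)
}

#' Multipoint parallel spiral search
#'
#' Runs the round-based portfolio framework: `k` random initial
#' self-avoiding walks are scored into a pool; each round the current
#' selection is distributed round-robin over the portfolio's workers, every
#' worker runs an independent spiral search (its guidance model per the
#' portfolio mix) from its assigned start, and at the round boundary all
#' workers' improving solutions are merged with the incoming pool,
#' deduplicated, rescored under the pool's evaluation model and the best
#' `k` are selected for the next round. Workers share no mutable state, so
#' the result is a deterministic function of
#' `(sequence, mix, rounds, budget, k, seed)` regardless of scheduling.
#'
#' @param sequence Residue string (amino-acid one-letter codes, or an H/P
#'   string for pure-HP portfolios).
#' @param mix A [portfolio_mix()] or its label; default `"PSSB1H3"`.
#' @param rounds Number of synchronisation rounds, >= 1.
#' @param budget Spiral-search iteration budget per start and round.
#' @param k Pool selection size; defaults to the number of workers (one
#'   start per worker and round).
#' @param seed Master seed; per-start worker seeds are split from it by a
#'   fixed rule (a seed table drawn once up front).
#' @param evaluation_model Pool scoring model: defaults to `"BM"` whenever
#'   the portfolio contains a BM-guided worker, `"HP"` for pure-HP mixes.
#' @param sequence_type See [search_state()].
#' @param symmetry Use symmetry-canonical deduplication keys.
#' @param ... Further arguments passed to [spiral_search()]
#'   (`max_stagnation`, `max_walks`, `walk_steps`).
#' @return An object of class `pss`: best conformation and score under the
#'   evaluation model, both energies of the best structure (when the
#'   sequence admits both), per-round history, seeds and configuration.
#' @examples
#' fit <- pss("HPHPPHHPHPPHPHHPPHPH", mix = "B0H4", rounds = 2,
#'            budget = 100, seed = 1)
#' fit$best_score
#' @export
pss <- function(sequence, mix = "PSSB1H3", rounds = 3L, budget = 1000L,
                k = NULL, seed = NULL, evaluation_model = NULL,
                sequence_type = c("auto", "aa", "hp"), symmetry = FALSE, ...) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  mix <- portfolio_mix(mix)
  workers <- mix$bm_workers + mix$hp_workers
  guidances <- c(rep("BM", mix$bm_workers), rep("HP", mix$hp_workers))
  rounds <- as.integer(rounds)
  if (rounds < 1L) stop("rounds must be >= 1")
  if (is.null(k)) k <- workers
  k <- as.integer(k)
  if (is.null(evaluation_model))
    evaluation_model <- if (mix$bm_workers > 0L) "BM" else "HP"
  sequence_type <- match.arg(sequence_type)
  is_hp_string <- grepl("^[HP]+$", sequence)
  if ((mix$bm_workers > 0L || evaluation_model == "BM") && is_hp_string &&
      sequence_type != "aa")
    stop("H/P strings admit only HP guidance and HP evaluation; ",
         "use a pure-HP mix (e.g. \"B0H4\") with evaluation_model = \"HP\"")

  if (!is.null(seed)) set.seed(seed)
  worker_seeds <- matrix(sample.int(.Machine$integer.max - 1L, rounds * k),
                         nrow = rounds, ncol = k)
  initial <- lapply(seq_len(k), function(j)
    conformation(sequence, random_saw(nchar(sequence)), validate = FALSE))

  pool <- merge_and_dedupe(list(initial), evaluation_model, symmetry)
  selection <- select_distinct_subset(pool, k, sequence = sequence)
  history <- vector("list", rounds)

  for (r in seq_len(rounds)) {
    contributions <- vector("list", k)
    worker_best <- numeric(k)
    for (j in seq_len(k)) {
      w <- ((j - 1L) %% workers) + 1L
      run <- .run_worker(selection[[j]], guidances[w], budget,
                         worker_seeds[r, j], sequence_type = sequence_type, ...)
      contributions[[j]] <- lapply(run$improving, function(m)
        conformation(sequence, m$coords, validate = FALSE))
      worker_best[j] <- run$best_energy
    }
    raw_size <- length(pool$members) + sum(lengths(contributions))
    pool <- merge_and_dedupe(c(list(lapply(pool$members, `[[`, "conf")),
                               contributions),
                             evaluation_model, symmetry)
    selection <- select_distinct_subset(pool, k, sequence = sequence)
    sel_scores <- vapply(selection, .score_conf, numeric(1),
                         model = evaluation_model)
    history[[r]] <- list(round = r,
                         merged_size = raw_size,
                         pool_size = length(pool$members),
                         worker_guidance = guidances[((seq_len(k) - 1L) %% workers) + 1L],
                         worker_best = worker_best,
                         selected_scores = sel_scores)
  }

  scores <- vapply(pool$members, `[[`, numeric(1), "score")
  best_i <- order(scores)[1L]
  best <- pool$members[[best_i]]$conf
  structure(list(
    sequence = sequence,
    mix = mix,
    rounds = rounds,
    budget = budget,
    k = k,
    seed = seed,
    worker_seeds = worker_seeds,
    evaluation_model = evaluation_model,
    initial = initial,
    best = best,
    best_score = scores[best_i],
    best_hp_energy = if (is_hp_string) hp_energy(best) else hp_energy(best, classify_hp(sequence)),
    best_bm_energy = if (is_hp_string) NA_real_ else bm_energy(best),
    pool = pool,
    history = history
  ), class = "pss")
}

#' @export
print.pss <- function(x, ...) {
  cat("Multipoint parallel spiral search (", x$mix$label, ")\n", sep = "")
  cat("  sequence length:", nchar(x$sequence),
      " rounds:", x$rounds, " budget/start:", x$budget, "\n")
  cat("  evaluation model:", x$evaluation_model,
      " best score:", x$best_score, "\n")
  cat("  final pool size:", length(x$pool$members), "\n")
  invisible(x)
}

#' @export
summary.pss <- function(object, ...) {
  print(object)
  for (h in object$history)
    cat(sprintf("  round %d: merged %d -> %d distinct, best selected %s\n",
                h$round, h$merged_size, h$pool_size,
                format(min(h$selected_scores))))
  invisible(object)
}

#' Plot per-round best pool scores of a parallel run
#'
#' @param x A `pss` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pss <- function(x, ...) {
  best_by_round <- vapply(x$history, function(h) min(h$selected_scores),
                          numeric(1))
  graphics::plot(seq_along(best_by_round), best_by_round, type = "b",
                 xlab = "round", ylab = paste(x$evaluation_model,
                                              "energy (best selected)"), ...)
  invisible(x)
}
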