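---
title: "Core-directed tabu spiral search on the FCC lattice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-directed tabu spiral search on the FCC lattice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralfold)
```

## The problem and the model

Ab initio protein structure prediction asks for the three-dimensional
conformation of a protein given only its amino-acid sequence, under the
hypothesis that the native structure minimises free energy. `spiralfold`
works in the classical simplified setting: the backbone is a self-avoiding
walk (SAW) on the face-centred-cubic (FCC) lattice, one lattice point per
residue, with consecutive residues on unit-distance lattice neighbours. The
FCC lattice is the densest of the common lattices and gives every point 12
neighbours, reached by the basis vectors `A`..`L` returned by
`fcc_basis_vectors()`; every walk is equivalently a string over that
12-letter alphabet (`encode_absolute()` / `decode_absolute()`), which the
package also uses as the translation-invariant identity of a conformation.

Two contact energy models score a conformation, both summing over
*nonconsecutive* residue pairs at unit lattice distance (squared Euclidean
distance 2):

* **HP model** (`hp_energy()`): residues are classed hydrophobic
  (G, A, P, V, L, I, M, F, Y, W) or polar (the other ten) by
  `classify_hp()`; each H–H contact contributes −1, everything else 0.
* **Contact-matrix model** (`bm_energy()`): each contact contributes the
  Berrera et al. (2003) empirical potential for the residue pair, a
  symmetric 20×20 table shipped as a lower-triangular text file and
  mirrored at load time (`bm_matrix()`). Entries may be positive; the
  strongest attraction is Cys–Cys at −3.477. Note that Cys is *polar* in
  the HP classification even though it carries the matrix minimum; apart
  from Cys, the large-magnitude attractions concentrate in the
  hydrophobic–hydrophobic block, which is what makes the coarse HP model a
  useful search heuristic for the fine-grained matrix.

Contacts are found by probing the 12 neighbours of every residue against a
per-conformation occupancy index rather than by an all-pairs scan; an
all-pairs oracle exists in the test suite and the two are required to agree
exactly.

## The spiral search

`spiral_search()` is a core-directed tabu local search. Its only structural
move is the **diagonal move** (corner flip, `diagonal_move()`): an interior
residue is relocated to a free lattice point that neighbours both of its
chain neighbours, which preserves the SAW invariant by construction.
Terminal residues have only one flank, so they never move; the chain ends
are still mobile indirectly through pull moves (below).

Under **HP guidance** the search alternates two phases:

1. *H phase.* The hydrophobic core centre (HCC) is the mean of the H
   residues' coordinates (`core_centre()`). For every non-tabu interior H
   residue, the free common neighbour of its flanks closest to the HCC is
   admitted if strictly closer to the HCC than the residue's current
   position; the globally best admitted candidate is applied
   (`select_h_move()`). This repeats — recomputing the HCC after every
   applied move — until no admissible H move remains, squeezing the chain
   inward in a spiral fashion.
2. *P phase.* Each interior polar residue gets one try: if it has free
   common flank neighbours, one is chosen uniformly at random and applied
   (`select_p_move()`). Polar relocations never change the HP energy
   directly (their contacts score 0); their role is to unblock new H moves.
   No centre, distance or tabu bookkeeping applies to them.

Under **BM guidance** (`select_move_bm()`) all residues are treated alike:
the centre is the centroid of the whole chain, every interior non-tabu
residue is a candidate, and each applied move is scored with the contact
matrix. This variant exists because a 20-letter model has no natural H/P
split; the centroid plays the role of the hydrophobic core centre.

**Tabu tenure.** A just-moved residue is unselectable for
`tabu_tenure(count) = floor(10 + count/10)` subsequent iterations, with
`count` the number of H residues under HP guidance. The tenure formula is
stated only for the hydrophobic count; since the matrix-guided variant
keeps a tabu entry for every residue, the package applies the same formula
to the total residue count there. That is an interpretation, recorded here
as such. There is no aspiration criterion: a tabu residue is never selected
even for an improving move.

**Stagnation handling.** Two mechanisms fire when the search stalls
(`max_stagnation = 200` applied moves without a new best, a threshold the
source procedure leaves open and which we fixed once at roughly four times
the tenure scale):

* a **random walk** of `walk_steps = 20` pull moves
  (`random_walk()`) breaks the premature core. Pull moves relocate a
  residue to a free point adjacent to itself and one chain neighbour, then
  drag the residues behind it into the vacated positions until the chain
  reconnects; every intermediate state is a valid SAW. Pull moves accept
  energy-worsening states unconditionally — they are an escape mechanism,
  not an optimiser. The walk length is enough to disrupt a local core
  without re-randomising the whole chain.
* if `max_walks = 2` consecutive walks fail to improve the best, a
  **relay restart** (`relay_restart()`) resumes from a uniformly drawn
  member of the improving-solution list — the ordered list of every
  conformation that improved the best-so-far — rather than from scratch or
  from the current best. The tabu list is cleared on both mechanisms.

**Budgets.** The testable core counts *iterations* (applied perturbations:
diagonal moves and pull-move steps), never wall-clock time, so every run is
a deterministic function of `(sequence, guidance, budget, seed, start)`.

## Numerical determinism

Move admission compares Euclidean distances to a coordinate *mean*. Done in
floating point, candidates that are exactly equidistant with the current
position (a frequent, geometrically exact event on a lattice) would be
admitted or rejected depending on summation order. The package therefore
compares `m^2 d^2 = sum((m p - s)^2)` — with `m` the subset size and `s`
the integer coordinate sums — which is exact integer arithmetic, so the
strict-improvement rule and all tie-breaks (lowest residue index, then
basis-vector order of the target) are reproducible across platforms.
Self-avoiding-walk generation (`random_saw()`) restarts from scratch on a
dead end, capped at 1000 attempts, rather than backtracking.

## The multipoint parallel framework

`pss()` runs the portfolio framework: `k` random SAWs seed a solution pool;
each round the current selection is distributed round-robin over the
portfolio's workers (`portfolio_mix()`: `PSSBxHy` = x matrix-guided plus y
HP-guided workers), every worker runs an independent `spiral_search()` from
its start, and at the round boundary the workers' improving solutions are
merged with the incoming pool, deduplicated and rescored
(`merge_and_dedupe()`), and the `k` best are selected for the next round
(`select_distinct_subset()`, topping up with fresh random walks if the pool
runs short).

Design choices that the round structure leaves open, fixed as follows:

* *Duplicate* means identical absolute move string — i.e. identical walks
  up to lattice translation. Canonicalising over the 48 point-group
  symmetries of the lattice is available (`canonical_key(symmetry = TRUE)`)
  but off by default: it is stricter and costlier, and translation identity
  already removes the duplicates that arise in practice.
* Mixed portfolios score the pool with the contact matrix (the finer
  evaluation model); pure-HP portfolios score with HP energy. An override
  exists. H/P instance strings admit only HP guidance and are refused
  under any matrix-guided worker rather than silently reread as His/Pro.
* Workers are pure functions of `(start, guidance, budget, seed)`; the
  per-start seeds are split from the master seed as a seed table drawn once
  up front, and each worker runs on an isolated RNG stream. Results are
  therefore identical under any execution order or scheduling, which the
  test suite checks by permuting worker order.
* `k` defaults to the worker count: one start per worker per round.

## The synthetic instance generator

`generate_random_instance(n, h_fraction)` draws i.i.d. Bernoulli H/P
letters. The default `h_fraction = 0.5` matches the hydrophobic fraction
typical of the classical HP benchmark instances. What the generator
emulates is only sequence *composition*: real proteins have correlated
hydrophobicity patterns (helical periodicity, hydrophobic clusters), so
passing tests on generated instances demonstrates the mechanics and the
comparative behaviour of the search, not predictive accuracy on natural
sequences. The twelve real benchmark sequences (`load_benchmarks()`) cover
the natural-sequence side for the contact-matrix model.

## Evaluation metrics

* `relative_improvement()` reports `100 (E_t - E_r) / (E_l - E_r)`, the
  fraction of the gap between a reference method's average energy `E_r`
  and the instance's lower bound of free energy `E_l` that the target
  method closes. The rounded variant rounds halves away from zero, which is
  the rule consistent with the published integer percentages
  (`ri_consistency_table()` recomputes them all and flags the rows whose
  printed integers are not internally consistent — one row, S3 against the
  single-thread reference, is irreproducible from the printed values and is
  flagged rather than forced).
* `drmsd()` is the superposition-free distance-matrix RMSD over all
  residue pairs. Lattice coordinates are scaled so that unit neighbours
  (√2 lattice units apart) map to the 3.8 Å CA–CA distance, i.e.
  3.8/√2 Å per lattice unit; the factor is a parameter. The scaling phrase
  in the source material ("the distance between two neighbour lattice
  points (2 for FCC lattice)") most plausibly refers to the *squared*
  distance 2, and the package implements this Euclidean reading.

## Problem sizes used by the test suite

The published benchmark energies come from 20–50 runs of one-to-five-hour
cluster executions; they are not reproducible at package-test scale. The
suite therefore checks exact worked examples, invariants, and a scaled-down
comparative experiment, with sizes chosen as follows:

* oracle equivalence of both energy models on 110 random walks of 10–200
  residues;
* determinism, monotonicity and tabu invariants over 20-seed sweeps on a
  generated 48-mer;
* the equal-CPU multipoint comparison on a generated 90-mer
  (`h_fraction = 0.5`): 20 seeded runs of a pure-HP four-worker portfolio
  (2 rounds × 2000 iterations per worker) against 20 single runs of 16000
  iterations, compared on mean best energy. The budget was placed where
  the single-run energy-versus-budget curve has flattened into the
  stagnation regime (beyond ~8000 iterations on this instance); in the
  steep early regime a single long run trivially beats any equal-budget
  split, and the multipoint advantage the framework is built around is a
  property of searches that have reached diminishing returns, as the
  hour-scale published runs had.

## Known limitations

* Only diagonal moves and pull moves are implemented; crankshaft, rotation
  and end-flip repertoires are out of scope, as are relative move
  encodings, side-chain models and non-FCC lattices.
* Terminal residues never move by diagonal moves (they lack a second
  flank); the source procedure defines no end move and we do not invent
  one.
* The framework is sequential-deterministic: "workers" are independent
  computations merged at round boundaries, not OS threads. Wall-clock
  budgets would break reproducibility and are deliberately absent from the
  core.
* Benchmark H counts printed alongside the contact-matrix results disagree
  by one with the stated H classification for some proteins (e.g. one
  54-residue homeodomain: 19 printed vs 20 classified); the package
  implements the stated classification verbatim.
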