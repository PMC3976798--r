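# spiralfold

Ab initio protein structure prediction on the 3D face-centred-cubic (FCC)
lattice, for researchers studying coarse-grained folding models and
portfolio metaheuristics. The package implements a core-directed tabu local
search ("spiral search") and a multipoint parallel framework that runs
mixed portfolios of the search's two guidance variants in rounds, merging
and reselecting improving solutions between rounds.

## The models and the algorithm

A conformation is a self-avoiding walk on the FCC lattice, one point per
residue; each point has 12 unit neighbours (basis vectors `A`..`L`). Two
contact energies score a conformation over all nonconsecutive residue pairs
(i, j), j > i + 1, at unit lattice distance (c<sub>ij</sub> = 1):

* **HP model**: E = Σ c<sub>ij</sub> e<sub>ij</sub> with e<sub>ij</sub> = −1
  when residues i and j are both hydrophobic
  (G, A, P, V, L, I, M, F, Y, W), else 0.
* **Contact-matrix (BM) model**: E = Σ c<sub>ij</sub> e<sub>ij</sub> with
  e<sub>ij</sub> the Berrera et al. (2003) empirical 20×20 contact
  potential for the residue pair.

The spiral search repeatedly applies diagonal (corner-flip) moves that pull
residues towards a core centre — the hydrophobic core centroid under HP
guidance, the chain centroid under matrix guidance — under a per-residue
tabu tenure `floor(10 + count/10)`, with pull-move random walks and
relay-restarts from the improving-solution list for stagnation recovery.
The parallel framework (`pss()`) distributes starting points over a worker
portfolio (`PSSBxHy` = x matrix-guided + y HP-guided workers), merges the
workers' improving solutions at round boundaries, removes duplicates by
translation-canonical move strings, rescores the pool (contact matrix
whenever a matrix-guided worker is present) and reselects the best k
starts for the next round. Everything is iteration-budgeted and seeded:
runs are exactly reproducible.

Evaluation utilities include the relative improvement
RI = 100 (E_t − E_r)/(E_l − E_r) against energy lower bounds, the
superposition-free distance-matrix RMSD (lattice units scaled by
3.8/√2 Å), benchmark fixtures, random H/P instance generation, FASTA and
H/P input, JSON reports and CA-trace PDB export.

## Worked example

```r
library(spiralfold)

seq54 <- load_benchmarks()$sequence[1]   # 4RXN, 54 residues
fit <- pss(seq54, mix = "B1H3", rounds = 2, budget = 500, seed = 42)
fit
#> Multipoint parallel spiral search (PSSB1H3)
#>   sequence length: 54  rounds: 2  budget/start: 500
#>   evaluation model: BM  best score: -101.622
#>   final pool size: 112
```

The best structure found scores −101.622 in contact-matrix units (the pool
evaluation model for a mixed portfolio; lower is better) and −39 under the
HP model (`fit$best_hp_energy`): 39 hydrophobic–hydrophobic lattice
contacts. `fit$best` holds the conformation (sequence, coordinates, move
string); `write_report(fit, "report.json")` serialises the run and
`export_pdb(fit$best, "best.pdb")` writes a CA trace with 3.8 Å bonds.

Published benchmark percentages recompute directly from the bundled
reference table:

```r
relative_improvement(-358, -350, -370, rounded = TRUE)   # instance S4
#> [1] 40
```

A command-line front end with the same options lives at
`inst/cli/pss.R` (`Rscript pss.R --input seq.fasta --mix B1H3 ...`).

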