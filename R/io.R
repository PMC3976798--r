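# Benchmark fixtures, sequence input, synthetic instance generation and
# JSON run reports.

.report_schema_version <- "1.0"

#' Bundled benchmark proteins
#'
#' The twelve standard benchmark proteins used for contact-matrix
#' evaluation (PDB-derived sequences of 54 to 160 residues), shipped as a
#' FASTA fixture.
#'
#' @return A data frame with columns `id`, `length`, `sequence`.
#' @examples
#' b <- load_benchmarks()
#' b[b$id == "4RXN", "length"]  # 54
#' @export
load_benchmarks <- function() {
  path <- system.file("extdata", "benchmark_proteins.fasta",
                      package = "spiralfold", mustWork = TRUE)
  seqs <- read_sequences(path, format = "fasta")
  ids <- sub(" .*", "", names(seqs))
  out <- data.frame(id = ids, length = nchar(unname(seqs)),
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  stated <- suppressWarnings(as.integer(sub(".*length=", "", names(seqs))))
  if (any(!is.na(stated) & stated != out$length))
    stop("corrupted benchmark fixture: sequence length disagrees with header")
  out
}

#' Published benchmark energies for the HP instances
#'
#' Reference table of best/average HP energies and energy lower bounds
#' (LBFE) for the 21 medium and large HP benchmark instances, as reported
#' for the parallel spiral search (PSS), single-thread spiral search
#' (SS-Tabu) and the genetic algorithm (GA+), together with the printed
#' rounded relative improvements. Used by [ri_consistency_table()] and the
#' reproduction script; the lower bound of one large instance (3on7) is
#' unknown (`NA`).
#'
#' @return A data frame, one row per instance.
#' @export
load_hp_benchmark_table <- function() {
  path <- system.file("extdata", "hp_benchmark_energies.tsv",
                      package = "spiralfold", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or plain H/P text
#'
#' FASTA is parsed with Biostrings (headers after `>`; wrapped sequence
#' lines concatenated; letters uppercased). The `hp-text` format holds one
#' H/P string per nonempty line.
#'
#' @param path Readable file.
#' @param format `"fasta"` or `"hp-text"`.
#' @return A character vector of uppercase sequences, named by FASTA
#'   headers where available.
#' @export
read_sequences <- function(path, format = c("fasta", "hp-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("read_sequences(format = \"fasta\") requires the Biostrings package")
    set <- Biostrings::readBStringSet(path)
    out <- toupper(as.character(set))
    if (any(nchar(out) == 0L)) stop("malformed FASTA: empty record")
    out
  } else {
    lines <- toupper(trimws(readLines(path)))
    lines <- lines[nchar(lines) > 0L]
    if (length(lines) == 0L) stop("no sequences in ", path)
    bad <- grepl("[^HP]", lines)
    if (any(bad))
      stop("hp-text sequences must use only H and P (line ", which(bad)[1], ")")
    lines
  }
}

#' Generate a random H/P instance
#'
#' Independent Bernoulli(h_fraction) draws per position: H with probability
#' `h_fraction`, else P.
#'
#' @param n Sequence length.
#' @param h_fraction Probability of a hydrophobic residue, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An H/P string of length `n`.
#' @examples
#' generate_random_instance(10, 0.5, seed = 1)
#' @export
generate_random_instance <- function(n, h_fraction = 0.5, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (h_fraction < 0 || h_fraction > 1) stop("h_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  paste(ifelse(stats::runif(n) < h_fraction, "H", "P"), collapse = "")
}

#' Write / read a JSON run report
#'
#' Serialises a [pss()] (or [spiral_search()]) result to a schema-versioned
#' JSON report: configuration echo, seeds, per-round summaries and the best
#' conformation (sequence, move string, coordinates, and its energy under
#' both models where the sequence admits both). `read_report()` restores
#' the report and reconstructs the best conformation exactly.
#'
#' @param fit A `pss` or `spiral_search` object.
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a list with the report fields and `best` as an
#'   `fcc_conformation`.
#' @export
write_report <- function(fit, path) {
  best <- if (inherits(fit, "pss")) fit$best
          else if (inherits(fit, "spiral_search")) fit$best
          else stop("fit must be a pss or spiral_search object")
  seq <- best$sequence
  is_hp_string <- grepl("^[HP]+$", seq)
  energies <- list(
    hp = hp_energy(best),
    bm = if (is_hp_string) NA_real_ else bm_energy(best)
  )
  report <- list(
    schema_version = .report_schema_version,
    kind = class(fit)[1],
    config = if (inherits(fit, "pss")) list(
      mix = fit$mix$label, rounds = fit$rounds, budget = fit$budget,
      k = fit$k, evaluation_model = fit$evaluation_model
    ) else list(
      guidance = fit$guidance, budget = fit$budget
    ),
    seed = fit$seed,
    worker_seeds = if (inherits(fit, "pss")) fit$worker_seeds else NULL,
    rounds = if (inherits(fit, "pss")) lapply(fit$history, function(h) list(
      round = h$round, merged_size = h$merged_size, pool_size = h$pool_size,
      worker_guidance = h$worker_guidance, worker_best = h$worker_best,
      selected_scores = h$selected_scores
    )) else NULL,
    best = list(
      sequence = seq,
      moves = encode_absolute(best$coords),
      coordinates = unname(best$coords),
      energy_hp = energies$hp,
      energy_bm = energies$bm,
      score = if (inherits(fit, "pss")) fit$best_score else fit$best_energy
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version))
    stop("not a run report: missing schema_version")
  rep$best_conformation <- conformation(
    rep$best$sequence,
    decode_absolute(rep$best$moves,
                    origin = rep$best$coordinates[1, ]))
  rep
}

#' Read native CA coordinates for dRMSD comparison
#'
#' Accepts either a whitespace-separated x y z table (one row per residue)
#' or a PDB file, from which CA atom records are extracted via bio3d.
#'
#' @param path Input file; treated as PDB when the extension is `.pdb` or
#'   `.ent` (case insensitive).
#' @return An n x 3 numeric coordinate matrix in Angstrom.
#' @export
read_native_coords <- function(path) {
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB files requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    ca <- bio3d::atom.select(pdb, elety = "CA")
    m <- matrix(pdb$xyz[ca$xyz], ncol = 3L, byrow = TRUE)
  } else {
    tab <- utils::read.table(path)
    if (ncol(tab) < 3L) stop("coordinate table must have 3 columns")
    m <- as.matrix(tab[, seq_len(3L)])
  }
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}
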