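# Independent brute-force oracles and small fixtures shared across tests.

# all-pairs O(n^2) contact enumeration from squared Euclidean distances
oracle_contact_pairs <- function(coords) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i + 1 && sum((coords[i, ] - coords[j, ])^2) == 2)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out
}

oracle_hp_energy <- function(hp, coords) {
  is_h <- strsplit(hp, "")[[1]] == "H"
  pr <- oracle_contact_pairs(coords)
  if (nrow(pr) == 0) return(0)
  -sum(is_h[pr[, 1]] & is_h[pr[, 2]])
}

oracle_bm_energy <- function(seq, coords) {
  aa <- strsplit(seq, "")[[1]]
  pr <- oracle_contact_pairs(coords)
  if (nrow(pr) == 0) return(0)
  sum(vapply(seq_len(nrow(pr)), function(r)
    bm_matrix_lookup(aa[pr[r, 1]], aa[pr[r, 2]]), numeric(1)))
}

# brute-force common free neighbours: intersect the full 12-neighbour sets
# of the two flanks, drop occupied points
oracle_cfn <- function(coords, i) {
  a <- fcc_neighbors(coords[i - 1, ])
  b <- fcc_neighbors(coords[i + 1, ])
  keys <- function(m) paste(m[, 1], m[, 2], m[, 3])
  common <- a[keys(a) %in% keys(b), , drop = FALSE]
  common[!(keys(common) %in% keys(coords)), , drop = FALSE]
}

# the corner 4-mer whose only nonconsecutive contact is (1, 4)
corner4 <- function(sequence = "HPPH") {
  conformation(sequence, rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1, -1, 0)))
}

random_hp_conformation <- function(n, h_fraction = 0.5) {
  conformation(generate_random_instance(n, h_fraction), random_saw(n),
               validate = FALSE)
}
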