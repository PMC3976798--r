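test_that("portfolio mix labels parse to worker counts", {
  m <- portfolio_mix("PSSB1H3")
  expect_equal(m$bm_workers, 1)
  expect_equal(m$hp_workers, 3)
  expect_identical(portfolio_mix("B0H4")$label, "PSSB0H4")
  m2 <- portfolio_mix(c(bm = 2, hp = 0))
  expect_identical(m2$label, "PSSB2H0")
  expect_error(portfolio_mix("B0H0"), "at least one worker")
  expect_error(portfolio_mix("quartet"), "unrecognised")
})

test_that("merging removes duplicates and rescoring follows the pool model", {
  a <- random_hp_conformation(20)
  b <- random_hp_conformation(20)
  pool <- merge_and_dedupe(list(list(a, a)), "HP")
  expect_equal(length(pool$members), 1)
  dis <- merge_and_dedupe(list(lapply(1:3, function(i) random_hp_conformation(15)),
                               lapply(1:2, function(i) random_hp_conformation(15))),
                          "HP")
  expect_equal(length(dis$members), 5)
  # translated copies collapse onto one canonical key
  shifted <- conformation(a$sequence, sweep(a$coords, 2, c(2L, 0L, 0L), "+"),
                          validate = FALSE)
  pool2 <- merge_and_dedupe(list(list(a), list(shifted)), "HP")
  expect_equal(length(pool2$members), 1)
  expect_identical(canonical_key(a), canonical_key(shifted))
  # scores come from the stated evaluation model
  expect_identical(pool$members[[1]]$score, hp_energy(a))
})

test_that("merging is idempotent and bounded by the input sizes", {
  set.seed(31)
  lists <- replicate(3, lapply(1:4, function(i) random_hp_conformation(12)),
                     simplify = FALSE)
  pool <- merge_and_dedupe(lists, "HP")
  expect_lte(length(pool$members), 12)
  again <- merge_and_dedupe(list(lapply(pool$members, `[[`, "conf")), "HP")
  expect_identical(vapply(again$members, `[[`, character(1), "key"),
                   vapply(pool$members, `[[`, character(1), "key"))
})

test_that("symmetry-canonical keys collapse rotated copies", {
  a <- random_hp_conformation(15)
  rot <- conformation(a$sequence, a$coords[, c(2, 3, 1)], validate = FALSE)
  expect_false(canonical_key(a) == canonical_key(rot) &&
                 !identical(a$coords, rot$coords))
  expect_identical(canonical_key(a, symmetry = TRUE),
                   canonical_key(rot, symmetry = TRUE))
  pool <- merge_and_dedupe(list(list(a), list(rot)), "HP", symmetry = TRUE)
  expect_equal(length(pool$members), 1)
})

test_that("subset selection takes the lowest scores and tops up when short", {
  set.seed(32)
  confs <- lapply(1:10, function(i) random_hp_conformation(25))
  pool <- merge_and_dedupe(list(confs), "HP")
  sel <- select_distinct_subset(pool, 4)
  sel_scores <- vapply(sel, hp_energy, integer(1))
  all_scores <- vapply(pool$members, `[[`, numeric(1), "score")
  expect_equal(sort(as.numeric(sel_scores)), sort(all_scores)[1:4])
  expect_true(max(sel_scores) <= min(setdiff(all_scores, sel_scores), Inf))
  small <- merge_and_dedupe(list(confs[1:2]), "HP")
  sel2 <- select_distinct_subset(small, 4)
  expect_equal(length(sel2), 4)
  expect_true(all(vapply(sel2, is_self_avoiding_walk, logical(1))))
})

test_that("a one-worker one-round portfolio equals a single spiral search", {
  hpseq <- generate_random_instance(30, 0.5, seed = 33)
  p <- pss(hpseq, mix = c(bm = 0, hp = 1), rounds = 1, budget = 200, seed = 11)
  ref <- spiral_search(budget = 200, seed = p$worker_seeds[1, 1],
                       start = p$initial[[1]])
  expect_identical(p$best_score, as.numeric(ref$best_energy))
  expect_identical(p$best$coords, ref$best$coords)
})

test_that("portfolio runs are deterministic and monotone over rounds", {
  hpseq <- generate_random_instance(40, 0.5, seed = 34)
  p1 <- pss(hpseq, mix = "B0H4", rounds = 2, budget = 100, seed = 3)
  p2 <- pss(hpseq, mix = "B0H4", rounds = 2, budget = 100, seed = 3)
  expect_identical(p1$best$coords, p2$best$coords)
  expect_identical(p1$best_score, p2$best_score)
  expect_identical(p1$history[[2]]$selected_scores,
                   p2$history[[2]]$selected_scores)
  # final best cannot be worse than the best initial solution
  init_scores <- vapply(p1$initial, hp_energy, integer(1))
  expect_lte(p1$best_score, min(init_scores))
  # per-round best selected scores are non-increasing
  bests <- vapply(p1$history, function(h) min(h$selected_scores), numeric(1))
  expect_true(all(diff(bests) <= 0))
})

test_that("worker execution order does not change the merged pool", {
  hpseq <- generate_random_instance(30, 0.5, seed = 35)
  starts <- lapply(1:4, function(i)
    conformation(hpseq, random_saw(30, seed = 40 + i), validate = FALSE))
  seeds <- c(101, 202, 303, 404)
  run_order <- function(ord) {
    res <- vector("list", 4)
    for (j in ord)
      res[[j]] <- spiral_search(budget = 150, seed = seeds[j],
                                start = starts[[j]])
    merge_and_dedupe(lapply(res, function(r)
      lapply(r$improving, function(m)
        conformation(hpseq, m$coords, validate = FALSE))), "HP")
  }
  keyset <- function(pool) sort(vapply(pool$members, `[[`, character(1), "key"))
  expect_identical(keyset(run_order(1:4)), keyset(run_order(4:1)))
})

test_that("mixed portfolios score pools with the contact matrix", {
  seq54 <- load_benchmarks()$sequence[1]
  p <- pss(seq54, mix = "B1H3", rounds = 1, budget = 80, seed = 6)
  expect_identical(p$evaluation_model, "BM")
  expect_identical(p$best_score, bm_energy(p$best))
  expect_false(is.na(p$best_hp_energy))
  # HP strings are refused when a BM worker is present
  expect_error(pss("HPHPHP", mix = "B1H3", rounds = 1, budget = 10, seed = 1),
               "pure-HP")
})
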