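test_that("core centre is the coordinate mean of the chosen residues", {
  conf <- conformation("HH", rbind(c(0, 0, 0), c(2, 2, 0)), validate = FALSE)
  expect_equal(core_centre(conf, 2), c(x = 2, y = 2, z = 0))
  expect_equal(core_centre(conf, 1:2), c(x = 1, y = 1, z = 0))
  w <- random_saw(20, seed = 2)
  conf20 <- conformation(strrep("H", 20), w, validate = FALSE)
  expect_equal(unname(core_centre(conf20, 1:20)), unname(colMeans(w)))
  expect_error(core_centre(conf, integer(0)), "empty")
  expect_error(core_centre(conf, 5), "range")
})

test_that("distance to centre is plain Euclidean distance", {
  expect_equal(distance_to_centre(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(distance_to_centre(c(1, 1, 0), c(0, 0, 0)), sqrt(2))
  expect_equal(distance_to_centre(c(3, 4, 0), c(0, 0, 0)), 5)
})

test_that("tabu tenure follows floor(10 + count/10)", {
  expect_identical(tabu_tenure(0), 10L)
  expect_identical(tabu_tenure(48), 14L)
  expect_identical(tabu_tenure(105), 20L)
  expect_error(tabu_tenure(-1), ">= 0")
})

# exhaustive per-residue enumeration, independent of the packaged scan
oracle_select <- function(st, h_only) {
  coords <- st$coords
  m <- length(st$centre_subset)
  s <- colSums(coords[st$centre_subset, , drop = FALSE])
  n <- nrow(coords)
  movable <- (2:(n - 1))[st$iteration >= st$tabu[2:(n - 1)]]
  if (h_only) movable <- movable[st$is_h[movable]]
  best <- NULL
  for (i in movable) {
    pts <- oracle_cfn(coords, i)
    if (nrow(pts) == 0) next
    nd2 <- (m * pts[, 1] - s[1])^2 + (m * pts[, 2] - s[2])^2 +
      (m * pts[, 3] - s[3])^2
    j <- which.min(nd2)
    od2 <- sum((m * coords[i, ] - s)^2)
    if (nd2[j] < od2 && (is.null(best) || nd2[j] < best$nd2))
      best <- list(residue = i, target = pts[j, ], nd2 = nd2[j])
  }
  best
}

test_that("core-directed move selection agrees with exhaustive enumeration", {
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(8:50, 1)
    if (rep %% 2 == 0) {
      conf <- conformation(paste(sample(rownames(bm_matrix()), n, replace = TRUE),
                                 collapse = ""), random_saw(n), validate = FALSE)
      st <- search_state(conf, "BM")
      got <- select_move_bm(st)
      want <- oracle_select(st, h_only = FALSE)
    } else {
      st <- search_state(random_hp_conformation(n), "HP")
      got <- select_h_move(st)
      want <- oracle_select(st, h_only = TRUE)
    }
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_identical(got$residue, want$residue)
      expect_identical(unname(got$target), unname(as.integer(want$target)))
      expect_lt(got$new_distance, got$old_distance)
    }
  }
})

test_that("fully tabu states yield no core-directed move", {
  st <- search_state(random_hp_conformation(20), "HP")
  st$tabu <- rep(1000L, 20L)
  expect_null(select_h_move(st))
  conf <- conformation(load_benchmarks()$sequence[1], random_saw(54, seed = 1),
                       validate = FALSE)
  stb <- search_state(conf, "BM")
  stb$tabu <- rep(1000L, 54L)
  expect_null(select_move_bm(stb))
})

test_that("the polar pass applies at most one try per polar residue, seeded", {
  conf <- random_hp_conformation(30)
  st1 <- search_state(conf, "HP"); set.seed(21)
  a <- select_p_move(st1)
  st2 <- search_state(conf, "HP"); set.seed(21)
  b <- select_p_move(st2)
  expect_identical(st1$coords, st2$coords)
  expect_equal(length(a), length(b))
  n_p_interior <- sum(!st1$is_h[2:29])
  expect_lte(length(a), n_p_interior)
  # all-H sequence has no polar residue to try
  all_h <- conformation(strrep("H", 20), random_saw(20, seed = 3),
                        validate = FALSE)
  expect_length(select_p_move(search_state(all_h, "HP")), 0)
})

test_that("relay restart resumes from the improving list deterministically", {
  fit <- spiral_search(generate_random_instance(40, 0.5, seed = 40),
                       budget = 300, seed = 2)
  st <- search_state(fit$best, "HP")
  st$improving <- fit$improving
  energies <- vapply(fit$improving, `[[`, numeric(1), "energy")
  set.seed(5); c1 <- relay_restart(st)
  expect_true(hp_energy(c1) %in% energies)
  expect_true(all(st$tabu == 0L))
  st2 <- search_state(fit$best, "HP")
  st2$improving <- fit$improving
  set.seed(5); c2 <- relay_restart(st2)
  expect_identical(c1$coords, c2$coords)
  # single-member list is a forced choice
  st$improving <- fit$improving[1]
  expect_identical(relay_restart(st)$coords, fit$improving[[1]]$coords)
})

test_that("zero budget evaluates the start and moves nothing", {
  conf <- random_hp_conformation(25)
  fit <- spiral_search(start = conf, budget = 0, seed = 1)
  expect_identical(fit$best$coords, conf$coords)
  expect_identical(fit$best_energy, hp_energy(conf))
  expect_equal(fit$iterations, 0)
})

test_that("spiral search is monotone, deterministic and SAW-preserving over seeds", {
  hpseq <- generate_random_instance(48, 0.5, seed = 48)
  for (s in 1:20) {
    fit <- spiral_search(hpseq, budget = 300, seed = s)
    expect_lte(fit$best_energy, fit$initial_energy)
    expect_true(is_self_avoiding_walk(fit$best))
    # improving-list energies strictly decrease
    imp <- vapply(fit$improving, `[[`, numeric(1), "energy")
    expect_true(all(diff(imp) < 0))
    # best-so-far profile is non-increasing in iteration order
    expect_true(all(diff(fit$improvements$energy) < 0))
  }
  f1 <- spiral_search(hpseq, budget = 300, seed = 7)
  f2 <- spiral_search(hpseq, budget = 300, seed = 7)
  expect_identical(f1$best$coords, f2$best$coords)
  expect_identical(f1$improvements, f2$improvements)
  expect_identical(f1$iterations, f2$iterations)
})

test_that("the trace respects tabu tenure for core-directed moves", {
  hpseq <- generate_random_instance(48, 0.5, seed = 48)
  tenure <- tabu_tenure(sum(strsplit(classify_hp(hpseq), "")[[1]] == "H"))
  fit <- spiral_search(hpseq, budget = 600, seed = 3, record_trace = TRUE)
  tr <- fit$trace
  hmoves <- tr[tr$event == "H-move", ]
  for (res in unique(hmoves$residue)) {
    its <- hmoves$iteration[hmoves$residue == res]
    if (length(its) > 1) expect_true(all(diff(its) > tenure))
  }
  # best-so-far column is non-increasing throughout
  expect_true(all(diff(tr$best_energy) <= 0))
})

test_that("BM-guided search runs on amino-acid sequences and improves", {
  seq54 <- load_benchmarks()$sequence[1]
  fit <- spiral_search(seq54, guidance = "BM", budget = 500, seed = 4)
  expect_lt(fit$best_energy, fit$initial_energy)
  expect_true(is_self_avoiding_walk(fit$best))
  f2 <- spiral_search(seq54, guidance = "BM", budget = 500, seed = 4)
  expect_identical(f2$best$coords, fit$best$coords)
  # H/P strings cannot be scored by the contact matrix
  expect_error(spiral_search("HPHP", guidance = "BM", budget = 10, seed = 1),
               "amino-acid")
})

test_that("the search reaches far lower energies than random walks", {
  hpseq <- generate_random_instance(48, 0.5, seed = 48)
  search_best <- vapply(1:20, function(s)
    as.numeric(spiral_search(hpseq, budget = 400, seed = s)$best_energy),
    numeric(1))
  random_e <- vapply(1:20, function(s)
    as.numeric(hp_energy(conformation(hpseq, random_saw(48, seed = 100 + s),
                                      validate = FALSE))),
    numeric(1))
  expect_lt(mean(search_best), mean(random_e))
})

test_that("an all-polar sequence under HP guidance still runs via polar moves", {
  fit <- spiral_search(strrep("P", 20), budget = 60, seed = 9)
  expect_identical(fit$best_energy, 0L)
  expect_true(is_self_avoiding_walk(fit$best))
})
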