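test_that("basis vectors have the FCC geometry", {
  B <- fcc_basis_vectors()
  expect_identical(dim(B), c(12L, 3L))
  expect_identical(rownames(B), LETTERS[1:12])
  # two nonzero +-1 components, squared length 2
  expect_true(all(rowSums(B != 0) == 2))
  expect_true(all(B %in% c(-1L, 0L, 1L)))
  expect_true(all(rowSums(B^2) == 2))
  expect_equal(nrow(unique(B)), 12)
  # closed under negation with the documented opposite pairs
  opp <- c(A = "J", B = "K", C = "L", D = "G", E = "H", F = "I")
  for (v in names(opp)) expect_equal(unname(B[v, ]), unname(-B[opp[[v]], ]))
})

test_that("fcc_neighbors returns the 12 unit neighbours, translation invariant", {
  nb0 <- fcc_neighbors(c(0, 0, 0))
  expect_equal(nrow(nb0), 12)
  expect_equal(nrow(unique(nb0)), 12)
  expect_true(any(apply(nb0, 1, function(p) all(p == c(1, 1, 0)))))
  expect_true(any(apply(nb0, 1, function(p) all(p == c(-1, 0, -1)))))
  expect_true(all(rowSums(nb0^2) == 2))
  shift <- c(1, 1, 0)
  expect_equal(unname(fcc_neighbors(shift)),
               unname(sweep(nb0, 2, shift, "+")))
})

test_that("self-avoiding-walk predicate accepts walks and rejects violations", {
  expect_true(is_self_avoiding_walk(rbind(c(0, 0, 0))))
  expect_true(is_self_avoiding_walk(rbind(c(0, 0, 0), c(1, 1, 0))))
  expect_false(is_self_avoiding_walk(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_false(is_self_avoiding_walk(rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0))))
})

test_that("random walks are valid, origin-anchored and seed-deterministic", {
  for (n in c(1, 2, 10, 50, 200)) {
    for (s in 1:8) {
      w <- random_saw(n, seed = s)
      expect_true(is_self_avoiding_walk(w))
      expect_equal(unname(w[1, ]), c(0L, 0L, 0L))
      expect_equal(nrow(w), n)
    }
  }
  expect_identical(random_saw(50, seed = 7), random_saw(50, seed = 7))
  w <- random_saw(500, seed = 1)
  expect_true(is_self_avoiding_walk(w))
})

test_that("absolute move encoding round-trips and flags bad input", {
  expect_identical(encode_absolute(rbind(c(0, 0, 0), c(1, 1, 0))), "A")
  for (s in 1:25) {
    w <- random_saw(sample(2:120, 1), seed = s)
    expect_identical(unname(decode_absolute(encode_absolute(w))), unname(w))
  }
  # decode away from the origin
  w <- random_saw(30, seed = 3)
  shifted <- sweep(w, 2, c(4L, 2L, 2L), "+")
  expect_identical(unname(decode_absolute(encode_absolute(shifted),
                                          origin = shifted[1, ])),
                   unname(shifted))
  # J is the inverse of A: decodes fine, fails the SAW check
  back <- decode_absolute("AJ")
  expect_identical(unname(back),
                   unname(rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L))))
  expect_false(is_self_avoiding_walk(back))
  expect_error(encode_absolute(rbind(c(0, 0, 0), c(2, 0, 0))), "basis")
  expect_error(decode_absolute("AXB"), "unknown move letter")
})

test_that("common free neighbours match the brute-force oracle", {
  set.seed(1)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    conf <- random_hp_conformation(n)
    i <- sample(2:(n - 1), 1)
    got <- common_free_neighbors(conf, i)
    want <- oracle_cfn(conf$coords, i)
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(got), key(want))
    # the moving residue's own position is occupied, hence never returned
    expect_false(paste(conf$coords[i, ], collapse = " ") %in%
                   paste(got[, 1], got[, 2], got[, 3]))
  }
})

test_that("flanks two steps apart along an axis admit the four diagonal points", {
  # flanks at (0,0,0) and (2,0,0): common neighbours are (1,+-1,0), (1,0,+-1)
  conf <- corner4()
  got <- common_free_neighbors(conf, 2)
  want <- rbind(c(1, 0, 1), c(1, 0, -1))  # (1,1,0) and (1,-1,0) are occupied
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(got), key(want))
  expect_error(common_free_neighbors(conf, 1), "interior")
  expect_error(common_free_neighbors(conf, 4), "interior")
})

test_that("conformation constructor validates and the text format round-trips", {
  expect_error(conformation("HP", rbind(c(0, 0, 0), c(2, 0, 0))),
               "self-avoiding")
  expect_error(conformation("HPP", rbind(c(0, 0, 0), c(1, 1, 0))), "length")
  conf <- random_hp_conformation(40)
  path <- withr::local_tempfile(fileext = ".txt")
  write_conformation(conf, path)
  back <- read_conformation(path)
  expect_identical(back$sequence, conf$sequence)
  expect_identical(unname(back$coords), unname(conf$coords))
})
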