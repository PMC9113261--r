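test_that("the three-gene worked instance gives ES = 1.5", {
  m <- matrix(c(3, 2, 1, 1, 2, 3), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- score_ssgsea(m, list(top = "g1"), alpha = 1)
  expect_equal(out$top[1], 1.5)            # P_in jumps to 1; P_out steps 0, .5, 1
  out0 <- score_ssgsea(m, list(top = "g1"), alpha = 0)
  expect_equal(out0$top[1], 1.5)           # singleton: weights cancel for any alpha
})

test_that("engine matches the brute-force running-sum oracle on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    N <- sample(5:50, 1)
    m <- rand_expr(N, 2)
    k <- sample(1:min(10, N - 1), 1)
    set <- sample(rownames(m), k)
    for (alpha in c(0, 0.25, 1)) {
      got <- score_ssgsea(m, list(s = set), alpha = alpha)$s
      want <- c(oracle_ssgsea(m[, 1], set, alpha), oracle_ssgsea(m[, 2], set, alpha))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("raw scores are invariant under strictly monotone per-sample transforms", {
  m <- rand_expr(40, 6, seed = 32)
  sets <- list(a = paste0("g", 1:8), b = paste0("g", 20:25))
  base <- score_ssgsea(m, sets)
  expect_equal(score_ssgsea(exp(m / 2), sets), base)
  expect_equal(score_ssgsea(m^3, sets), base)   # values > 0, strictly increasing
})

test_that("range normalization rescales columns as documented", {
  m <- rand_expr(30, 10, seed = 33)
  sets <- list(a = paste0("g", 1:5), b = paste0("g", 10:18))
  raw <- score_ssgsea(m, sets, norm = "raw")
  sep <- score_ssgsea(m, sets, norm = "separate")
  expect_equal(sep$a, raw$a / diff(range(raw$a)))
  expect_equal(sep$b, raw$b / diff(range(raw$b)))
  glob <- score_ssgsea(m, sets, norm = "all")
  rng <- diff(range(c(raw$a, raw$b)))
  expect_equal(glob$a, raw$a / rng)
  expect_equal(glob$b, raw$b / rng)
})

test_that("degenerate sets are rejected or flagged", {
  m <- rand_expr(5, 4, seed = 34)
  expect_error(score_ssgsea(m, list(everything = rownames(m))), "covering every gene")
  expect_warning(out <- score_ssgsea(m, list(gone = "nope")), "no genes present")
  expect_true(all(is.na(out$gone)))
  expect_error(score_ssgsea(m, list(a = "g1"), alpha = -1), "non-negative")
  # zero range: single signature constant across samples is impossible with
  # continuous data, so force it via duplicated sample values
  m2 <- cbind(s1 = m[, 1], s2 = m[, 1])
  expect_error(score_ssgsea(m2, list(a = "g1"), norm = "separate"), "zero score range")
})
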