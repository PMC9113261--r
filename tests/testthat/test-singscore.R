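test_that("top-ranked sets score 1 and bottom-ranked sets score 0 (uncentered)", {
  m <- rand_expr(5, 1, seed = 41)
  r <- rank(m[, 1])
  top2 <- names(sort(r, decreasing = TRUE))[1:2]
  bot2 <- names(sort(r))[1:2]
  expect_equal(score_singscore(m, list(s = top2), center = FALSE)$s, 1)
  expect_equal(score_singscore(m, list(s = bot2), center = FALSE)$s, 0)
})

test_that("bidirectional sets hitting both extremes total 1 when centered", {
  m <- rand_expr(10, 1, seed = 42)
  r <- rank(m[, 1])
  up <- names(sort(r, decreasing = TRUE))[1:3]
  down <- names(sort(r))[1:2]
  out <- score_singscore(m, list(s = list(up = up, down = down)), center = TRUE)
  expect_equal(out$s, 1)
  out_un <- score_singscore(m, list(s = list(up = up, down = down)), center = FALSE)
  expect_equal(out_un$s, 2)
})

test_that("up-scores equal the mean-rank oracle on random instances", {
  set.seed(43)
  for (rep in 1:60) {
    N <- sample(5:50, 1)
    m <- rand_expr(N, 2)
    k <- sample(1:(N - 1), 1)
    set <- sample(rownames(m), k)
    got <- score_singscore(m, list(s = set), center = FALSE)$s
    want <- c(oracle_singscore_up(m[, 1], set), oracle_singscore_up(m[, 2], set))
    expect_equal(got, want, tolerance = 1e-12)
    got_c <- score_singscore(m, list(s = set), center = TRUE)$s
    expect_equal(got_c, want - 0.5, tolerance = 1e-12)
  }
})

test_that("scores are invariant under strictly monotone per-sample transforms", {
  m <- rand_expr(30, 5, seed = 44)
  sets <- list(s = list(up = paste0("g", 1:6), down = paste0("g", 20:24)))
  base <- score_singscore(m, sets)
  expect_equal(score_singscore(exp(m / 3), sets), base)
})

test_that("the abs-median-centered mode ranks distance from the sample median", {
  m <- rand_expr(15, 3, seed = 45)
  sets <- list(s = paste0("g", 1:4))
  alt <- score_singscore(m, sets, undirected = "abs_median_centered", center = FALSE)
  # manual recomputation for sample 1
  x <- m[, 1]
  want <- oracle_singscore_up(stats::setNames(abs(x - median(x)), names(x)),
                              paste0("g", 1:4))
  expect_equal(alt$s[1], want)
})

test_that("spanning and absent sets are handled per contract", {
  m <- rand_expr(5, 3, seed = 46)
  expect_error(score_singscore(m, list(s = rownames(m))), "spanning")
  expect_warning(out <- score_singscore(m, list(s = "absent")), "no up genes")
  expect_true(all(is.na(out$s)))
  expect_warning(
    out2 <- score_singscore(m, list(s = list(up = "g1", down = "nope"))),
    "down gene list fully absent")
  expect_equal(out2$s, score_singscore(m, list(s = "g1"))$s)
})
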