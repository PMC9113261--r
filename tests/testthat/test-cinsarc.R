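test_that("well-separated classes are recovered perfectly and match the oracle", {
  sim <- simulate_two_classes(n_genes = 10, n_per_class = 10, delta = 4, seed = 111)
  out <- classify_cinsarc(sim$expr, sim$labels, genes = rownames(sim$expr))
  want <- ifelse(sim$labels$status == 0, "C1", "C2")
  expect_identical(out$risk_class, want)
  expect_identical(out$risk_class, oracle_cinsarc(sim$expr, sim$labels$status))
})

test_that("classification agrees with the brute-force LOOCV oracle on random instances", {
  set.seed(112)
  for (i in 1:25) {
    n_per <- sample(2:15, 1)
    n_genes <- sample(2:20, 1)
    sim <- simulate_two_classes(n_genes, n_per, delta = runif(1, 0, 2),
                                seed = sample.int(1e6, 1))
    got <- classify_cinsarc(sim$expr, sim$labels, genes = rownames(sim$expr))
    expect_identical(got$risk_class, oracle_cinsarc(sim$expr, sim$labels$status))
  }
})

test_that("ties in centroid distance go to the high-risk class", {
  # two genes; classes mirror-symmetric so the probe sample is equidistant
  m <- matrix(c(-1, -1, -1.5, -0.5, 1, 1, 1.5, 0.5, 0, 0),
              nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:5)))
  labels <- tibble::tibble(sample_id = paste0("s", 1:5),
                           status = c(0, 0, 1, 1, 0))
  out <- classify_cinsarc(m, labels, genes = c("g1", "g2"))
  d <- out[out$sample_id == "s5", ]
  expect_equal(d$dist_lowrisk, d$dist_highrisk)
  expect_identical(d$risk_class, "C2")
})

test_that("swapping the status coding swaps every C1 and C2 call", {
  sim <- simulate_two_classes(n_genes = 8, n_per_class = 6, delta = 1, seed = 113)
  a <- classify_cinsarc(sim$expr, sim$labels, genes = rownames(sim$expr))
  flipped <- dplyr::mutate(sim$labels, status = 1 - status)
  b <- classify_cinsarc(sim$expr, flipped, genes = rownames(sim$expr))
  expect_identical(b$risk_class, ifelse(a$risk_class == "C1", "C2", "C1"))
})

test_that("label gaps, tiny classes and absent genes are rejected", {
  sim <- simulate_two_classes(n_genes = 5, n_per_class = 3, seed = 114)
  expect_error(classify_cinsarc(sim$expr, sim$labels[-1, ], genes = rownames(sim$expr)),
               "missing metastasis label")
  bad <- sim$labels; bad$status <- c(0, rep(1, 5))
  expect_error(classify_cinsarc(sim$expr, bad, genes = rownames(sim$expr)),
               "at least 2 samples")
  expect_error(classify_cinsarc(sim$expr, sim$labels, genes = "nope"),
               "no signature genes")
})

test_that("per-fold restandardization is available and still recovers clear classes", {
  sim <- simulate_two_classes(n_genes = 10, n_per_class = 8, delta = 4, seed = 115)
  out <- classify_cinsarc(sim$expr, sim$labels, genes = rownames(sim$expr),
                          restandardize = TRUE)
  expect_identical(out$risk_class, ifelse(sim$labels$status == 0, "C1", "C2"))
})
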