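test_that("cohort generation is bit-identical per seed and leaves global RNG alone", {
  a <- simulate_spike_cohort(n_genes = 50, n_samples = 10, set_size = 5, seed = 9)
  b <- simulate_spike_cohort(n_genes = 50, n_samples = 10, set_size = 5, seed = 9)
  expect_identical(a, b)
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulate_spike_cohort(n_genes = 20, n_samples = 4,
                                               set_size = 3, seed = 42))
  expect_identical(rnorm(3), before)
  c1 <- simulate_two_classes(seed = 5)
  c2 <- simulate_two_classes(seed = 5)
  expect_identical(c1, c2)
})

test_that("zero effect size produces exchangeable groups", {
  # two-sample t-test on set-gene means, 50 replicate seeds, alpha = 0.01:
  # false positives should stay near the nominal rate
  pvals <- vapply(1:50, function(seed) {
    sim <- simulate_spike_cohort(n_genes = 60, n_samples = 30, set_size = 10,
                                 effect_size = 0, seed = seed)
    gm <- colMeans(sim$expr[sim$gene_set, ])
    stats::t.test(gm[sim$labels$spiked], gm[!sim$labels$spiked])$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 5)  # expect ~0.5 rejections; 5 is far out in the tail
})

test_that("a strong spike is detected by the combined z-score in every replicate", {
  hits <- vapply(1:20, function(seed) {
    sim <- simulate_spike_cohort(n_genes = 100, n_samples = 40, set_size = 20,
                                 effect_size = 5, seed = seed)
    sc <- score_zscore(sim$expr, list(s = sim$gene_set))$s
    mean(sc[sim$labels$spiked]) > mean(sc[!sim$labels$spiked])
  }, logical(1))
  expect_true(all(hits))
})

test_that("invalid designs are rejected", {
  expect_error(simulate_spike_cohort(n_genes = 5, set_size = 5), "smaller")
  expect_error(simulate_spike_cohort(spiked_fraction = 1), "between 0 and 1")
  expect_error(simulate_two_classes(n_per_class = 1), "at least 2")
})

test_that("class separation behaves as designed at the extremes", {
  # delta = 4: perfect LOOCV recovery; delta = 0: near-chance accuracy
  acc <- function(delta, seed) {
    sim <- simulate_two_classes(n_genes = 10, n_per_class = 10, delta = delta,
                                seed = seed)
    out <- classify_cinsarc(sim$expr, sim$labels, genes = rownames(sim$expr))
    mean(out$risk_class == ifelse(sim$labels$status == 0, "C1", "C2"))
  }
  expect_true(all(vapply(1:10, function(s) acc(4, s), numeric(1)) == 1))
  null_acc <- mean(vapply(1:10, function(s) acc(0, s), numeric(1)))
  expect_gt(null_acc, 0.3)
  expect_lt(null_acc, 0.7)
})
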