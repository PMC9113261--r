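demo_ips_config <- function() {
  list(
    list(name = "m_mhc", category = "MHC", weight = 1, genes = c("A1", "A2")),
    list(name = "m_ec",  category = "EC",  weight = 1, genes = c("B1")),
    list(name = "m_sc",  category = "SC",  weight = -1, genes = c("C1")),
    list(name = "m_cp",  category = "CP",  weight = -1, genes = c("D1"))
  )
}

config_expr <- function(n_samples = 6, seed = 121) {
  genes <- c("A1", "A2", "B1", "C1", "D1", paste0("x", 1:5))
  set.seed(seed)
  matrix(rnorm(length(genes) * n_samples, 6, 1), length(genes), n_samples,
         dimnames = list(genes, paste0("s", seq_len(n_samples))))
}

test_that("a constant cohort gives zero z-scores everywhere and IPS 0", {
  m <- config_expr()
  m[] <- 5
  out <- score_ips(m, config = demo_ips_config())
  expect_true(all(out$az == 0))
  expect_true(all(out$ips == 0L))
})

test_that("the aggregate score is the sum of the category scores and scales to 0-10", {
  m <- config_expr(seed = 122)
  out <- score_ips(m, config = demo_ips_config())
  expect_equal(out$az, out$MHC + out$EC + out$SC + out$CP)
  expect_true(all(out$ips %in% 0:10))
  expect_true(all(out$ips[out$az <= 0] == 0L))
  pos <- out$az > 0
  expect_equal(out$ips[pos],
               as.integer(pmin(10, floor(out$az[pos] * 10 / 3 + 0.5))))
})

test_that("constructed aggregate scores hit the stated branches", {
  # Build a cohort where one sample has z = +1 for all positive-marker genes
  # and z = -1 for negative-marker genes, giving az = 1 + 1 + 1 + 1 = wait:
  # categories MHC/EC get +1, SC/CP markers score -1 with weight -1 -> +1.
  # Check the mapping function directly on engineered az instead.
  m <- config_expr(n_samples = 4, seed = 123)
  out <- score_ips(m, config = demo_ips_config())
  # mapping checks on the documented formula
  map_ips <- function(az) ifelse(az <= 0, 0, pmin(10, floor(az * 10 / 3 + 0.5)))
  expect_equal(map_ips(3), 10)
  expect_equal(map_ips(-1), 0)
  expect_equal(map_ips(1.5), 5)
  # and the engine result obeys it sample by sample
  expect_equal(out$ips, as.integer(map_ips(out$az)))
})

test_that("IPS is invariant to adding a constant to all expression values", {
  m <- config_expr(seed = 124)
  cfg <- demo_ips_config()
  expect_equal(score_ips(m, cfg), score_ips(m + 2.5, cfg))
})

test_that("missing markers are dropped with warning; empty categories error", {
  m <- config_expr(seed = 125)
  cfg <- c(demo_ips_config(),
           list(list(name = "gone", category = "EC", weight = 1, genes = "ZZZ")))
  expect_warning(out <- score_ips(m, cfg), "dropping marker")
  expect_false("gone" %in% names(out))
  cfg2 <- demo_ips_config()
  cfg2[[2]]$genes <- "ZZZ"  # the only EC marker
  expect_error(suppressWarnings(score_ips(m, cfg2)), "category: EC")
})

test_that("the bundled marker table scores a matching cohort end to end", {
  genes <- unique(unlist(purrr::map(
    yaml::read_yaml(system.file("signatures", "ips-synthetic.yml",
                                package = "sigscore"))$markers, "genes")))
  set.seed(126)
  m <- matrix(rnorm(length(genes) * 10, 6, 1), length(genes), 10,
              dimnames = list(genes, paste0("s", 1:10)))
  out <- score_ips(m)
  expect_true(all(c("MHC", "EC", "SC", "CP", "az", "ips") %in% names(out)))
  expect_true(all(out$ips %in% 0:10))
})
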