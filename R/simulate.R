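#' Simulate an expression cohort with a spiked-in signature
#'
#' Generates a deterministic synthetic cohort for validating the scoring
#' engines: baseline expression is i.i.d. Gaussian on a log2-like scale
#' (mean 6, sd 1); the genes of one designated set are shifted upward by
#' `effect_size` standard deviations in a "spiked" subgroup of samples. With
#' `effect_size = 0` the spiked and unspiked groups are draws from the same
#' distribution. All randomness flows from `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param set_size Number of genes in the spiked signature
#'   (`set_size < n_genes`).
#' @param spiked_fraction Fraction of samples in the spiked group, strictly
#'   between 0 and 1.
#' @param effect_size Mean shift applied to set genes in spiked samples, in
#'   baseline-sd units.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param base_mean,base_sd Baseline Gaussian parameters.
#' @return A list with `expr` (matrix, genes x samples), `gene_set`
#'   (character), and `labels` (tibble `sample_id`, `spiked`).
#' @examples
#' sim <- simulate_spike_cohort(n_genes = 50, n_samples = 10, set_size = 5, seed = 1)
#' dim(sim$expr)
#' @export
simulate_spike_cohort <- function(n_genes = 100, n_samples = 40, set_size = 20,
                                  spiked_fraction = 0.5, effect_size = 2,
                                  seed = 1, base_mean = 6, base_sd = 1) {
  if (set_size >= n_genes) abort("`set_size` must be smaller than `n_genes`.")
  if (spiked_fraction <= 0 || spiked_fraction >= 1) {
    abort("`spiked_fraction` must be strictly between 0 and 1.")
  }
  if (n_genes < 2L || n_samples < 2L) abort("need at least 2 genes and 2 samples.")
  with_local_seed(seed, {
    expr <- matrix(rnorm(n_genes * n_samples, base_mean, base_sd),
                   nrow = n_genes, ncol = n_samples,
                   dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                                   sprintf("sample%03d", seq_len(n_samples))))
    n_spiked <- max(1L, min(n_samples - 1L, round(spiked_fraction * n_samples)))
    spiked <- sample(n_samples, n_spiked)
    set_genes <- sample(rownames(expr), set_size)
    expr[set_genes, spiked] <- expr[set_genes, spiked] + effect_size * base_sd
    list(
      expr = expr,
      gene_set = set_genes,
      labels = tibble::tibble(sample_id = colnames(expr),
                              spiked = seq_len(n_samples) %in% spiked)
    )
  })
}

#' Simulate two Gaussian classes for nearest-centroid validation
#'
#' Two equal-size groups of samples drawn from per-gene Gaussians whose means
#' differ by `delta` standard deviations for every gene; group 1 carries
#' metastasis status 1. `delta = 0` makes the classes indistinguishable.
#' Deterministic in `seed`.
#'
#' @param n_genes Number of genes.
#' @param n_per_class Samples per class (at least 2).
#' @param delta Class separation per gene, in sd units.
#' @param seed Integer seed.
#' @return A list with `expr` (matrix) and `labels` (tibble `sample_id`,
#'   `status` coded 0/1).
#' @export
simulate_two_classes <- function(n_genes = 20, n_per_class = 10, delta = 4,
                                 seed = 1) {
  if (n_per_class < 2L) abort("`n_per_class` must be at least 2.")
  if (n_genes < 1L) abort("need at least 1 gene.")
  with_local_seed(seed, {
    n <- 2L * n_per_class
    expr <- matrix(rnorm(n_genes * n, 6, 1), nrow = n_genes,
                   dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                                   sprintf("sample%03d", seq_len(n))))
    status <- rep(c(0, 1), each = n_per_class)
    expr[, status == 1] <- expr[, status == 1] + delta
    list(expr = expr,
         labels = tibble::tibble(sample_id = colnames(expr), status = status))
  })
}
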