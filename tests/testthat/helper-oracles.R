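# Independent brute-force oracles used to validate the engines. These are
# written as literal walks over explicit arrays, separate from the package
# implementations.

# ssGSEA: explicit running-sum walk with materialized P_in / P_out arrays.
# Assumes no ties in `x` (oracle instances are continuous draws).
oracle_ssgsea <- function(x, set_genes, alpha) {
  N <- length(x)
  r <- rank(x)
  ord <- order(x, decreasing = TRUE)
  genes <- names(x)[ord]
  in_set <- genes %in% set_genes
  m <- sum(in_set)
  stopifnot(m >= 1, m < N)
  total_w <- sum(r[genes[in_set]]^alpha)
  p_in <- numeric(N)
  p_out <- numeric(N)
  for (i in seq_len(N)) {
    p_in[i] <- (if (i > 1) p_in[i - 1] else 0) +
      (if (in_set[i]) r[genes[i]]^alpha / total_w else 0)
    p_out[i] <- (if (i > 1) p_out[i - 1] else 0) +
      (if (!in_set[i]) 1 / (N - m) else 0)
  }
  sum(p_in - p_out)
}

# singscore up-score by direct evaluation of the normalized mean rank.
oracle_singscore_up <- function(x, set_genes, center = FALSE) {
  N <- length(x)
  n <- length(set_genes)
  mean_rank <- mean(rank(x)[set_genes])
  r_min <- (n + 1) / 2
  r_max <- (2 * N - n + 1) / 2
  s <- (mean_rank - r_min) / (r_max - r_min)
  if (center) s - 0.5 else s
}

# Leave-one-out nearest-centroid classification, written with plain loops
# and stats::scale for the standardization.
oracle_cinsarc <- function(mat, status) {
  z <- t(scale(t(mat)))
  z[!is.finite(z)] <- 0
  n <- ncol(z)
  out <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    c0 <- rowMeans(z[, tr[status[tr] == 0], drop = FALSE])
    c1 <- rowMeans(z[, tr[status[tr] == 1], drop = FALSE])
    d0 <- sqrt(sum((z[, i] - c0)^2))
    d1 <- sqrt(sum((z[, i] - c1)^2))
    out[i] <- if (d0 < d1) "C1" else "C2"
  }
  out
}

# Random continuous expression matrix with named genes/samples.
rand_expr <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}
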