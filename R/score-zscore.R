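#' Combined z-score signature scores
#'
#' Standardizes every gene across the cohort (sample mean 0, sample standard
#' deviation 1, divisor n - 1) and scores each signature in each sample as the
#' sum of the z-values of its genes divided by the square root of the number of
#' signature genes found in the matrix. Directionality is ignored: up and down
#' gene lists are pooled. Genes that are constant across samples get z = 0
#' (with a warning) instead of failing the run; signatures with no genes in
#' the matrix yield an `NA` column with a warning.
#'
#' @param expr_data Expression table accepted by [as_expr_matrix()].
#' @param signatures Named list of gene sets: character vectors or
#'   `list(up =, down =)` elements.
#' @param workers Number of parallel workers; the result is identical for any
#'   value.
#' @return A tibble with one row per sample: `sample_id` plus one score column
#'   per signature.
#' @examples
#' m <- matrix(c(1, 2, 3, 6), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' score_zscore(m, list(sig = c("g1", "g2")))
#' @export
score_zscore <- function(expr_data, signatures, workers = 1L) {
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  sigs <- as_sig_list(signatures)

  mu <- rowMeans(mat)
  sdev <- apply(mat, 1L, sd)
  zero_var <- sdev == 0 | !is.finite(sdev)
  if (any(zero_var)) {
    warn(paste0(sum(zero_var), " gene(s) with zero variance; their z-scores are set to 0."))
    sdev[zero_var] <- 1
  }
  z <- (mat - mu) / sdev
  z[zero_var, ] <- 0

  members <- purrr::map(sigs, function(s) intersect(union(s$up, s$down), rownames(mat)))
  empty <- purrr::map_lgl(members, ~ length(.x) == 0L)
  if (any(empty)) {
    warn(paste0("no genes present for signature(s): ",
                paste(names(sigs)[empty], collapse = ", "), "; scores set to NA."))
  }

  score_one <- function(zcol) {
    vapply(members, function(g) {
      if (length(g) == 0L) return(NA_real_)
      sum(zcol[g]) / sqrt(length(g))
    }, numeric(1))
  }
  scores_to_tbl(per_sample_apply(z, score_one, workers), names(sigs))
}
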