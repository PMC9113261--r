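#' Check signature gene coverage in an expression matrix
#'
#' Before scoring, audit how well each signature is represented: the number of
#' signature genes, how many are present in the matrix, the fraction present,
#' and the missing symbols. A coverage of zero is a valid report row, not an
#' error.
#'
#' @inheritParams score_zscore
#' @param signatures `"all"` (default), a character vector of registry
#'   keywords, or a named list of custom gene sets.
#' @param exact Passed to the registry keyword matcher, see [sig_genes()].
#' @return A tibble with columns `signature_id`, `n_genes`, `n_present`,
#'   `frac_present` and a list-column `missing_genes`. Always satisfies
#'   `n_present + lengths(missing_genes) == n_genes` and
#'   `frac_present == n_present / n_genes`.
#' @examples
#' m <- matrix(rnorm(6, 6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' check_sig(m, list(my_set = c("A", "B", "D")))
#' @export
check_sig <- function(expr_data, signatures = "all", exact = FALSE) {
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  sigs <- if (is.character(signatures)) {
    registry_select(signatures, exact = exact)
  } else {
    as_sig_list(signatures)
  }
  rows <- purrr::map(sigs, function(s) {
    genes <- union(s$up, s$down)
    miss <- setdiff(genes, rownames(mat))
    tibble::tibble(
      signature_id = s$id,
      n_genes = length(genes),
      n_present = length(genes) - length(miss),
      frac_present = (length(genes) - length(miss)) / length(genes),
      missing_genes = list(miss)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("sig_coverage", class(out)))
  out
}
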