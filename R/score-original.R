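#' Original-procedure signature scores (mean and weighted sum)
#'
#' Two archetypes cover most published signature scoring procedures: the
#' arithmetic mean of the expression of the signature genes, and a weighted
#' sum of expression against published per-gene model coefficients. This
#' function evaluates either archetype per sample.
#'
#' For `weighted_sum`, coefficient terms whose gene is absent from the matrix
#' are dropped with a warning (use [check_sig()] to audit coverage before
#' scoring). A signature with no genes present yields an `NA` column.
#'
#' @inheritParams score_zscore
#' @param signatures Named list of signature definitions; each element is
#'   either a character vector (scored by `mean`) or a list with `up` (and
#'   optional `down`) genes, a `method` of `"mean"` or `"weighted_sum"`, and
#'   for the latter a named `coefficients` vector covering every gene.
#' @return A tibble, one row per sample, one score column per signature.
#' @examples
#' m <- matrix(c(2, 4, 1, 3), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' score_original(m, list(avg = c("g1", "g2")))
#' @export
score_original <- function(expr_data, signatures, workers = 1L) {
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  sigs <- as_sig_list(signatures)
  bad <- purrr::map_lgl(sigs, ~ .x$method %!in% c("mean", "weighted_sum"))
  if (any(bad)) {
    abort(paste0("signature(s) without a mean/weighted_sum original procedure: ",
                 paste(names(sigs)[bad], collapse = ", "),
                 ". Use sig_score() (which dispatches ssGSEA-style originals) or the dedicated scorers."))
  }

  col_scores <- purrr::map(sigs, function(s) {
    genes <- union(s$up, s$down)
    pres <- intersect(genes, rownames(mat))
    if (length(pres) == 0L) {
      warn(paste0("no genes present for signature '", s$id, "'; scores set to NA."))
      return(rep(NA_real_, ncol(mat)))
    }
    if (s$method == "mean") {
      colMeans(mat[pres, , drop = FALSE])
    } else {
      miss <- setdiff(genes, pres)
      if (length(miss) > 0L) {
        warn(paste0("signature '", s$id, "': dropping ", length(miss),
                    " coefficient term(s) for absent gene(s)."))
      }
      drop(s$coefficients[pres] %*% mat[pres, , drop = FALSE])
    }
  })

  out <- tibble::tibble(sample_id = colnames(mat))
  for (id in names(sigs)) out[[id]] <- unname(col_scores[[id]])
  new_score_tbl(out)
}
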