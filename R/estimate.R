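#' ESTIMATE-style immune, stromal and tumor purity scores
#'
#' Scores an immune and a stromal infiltration gene set per sample with raw
#' ssGSEA (alpha = 0.25), sums them into the combined score, and maps that sum
#' to a tumor purity estimate through the cosine relation
#' `purity = cos(a + b * estimate_score)`. The relation is only meaningful on
#' the monotone-decreasing branch of the cosine (argument within \[0, pi\]);
#' samples whose argument leaves that branch get `NA` purity with a warning,
#' and purity values are clamped to \[0, 1\].
#'
#' The default coefficients `(a, b)` are the published calibration for this
#' method. The default bundled gene sets are synthetic demonstration stand-ins
#' for the published 141-gene lists (see their registry descriptions); supply
#' `immune_genes` / `stroma_genes` for faithful scores.
#'
#' @inheritParams score_zscore
#' @param immune_genes,stroma_genes Character vectors of HUGO symbols;
#'   defaults come from the bundled registry.
#' @param purity_coef Numeric vector `c(a, b)` of cosine coefficients, or
#'   `NULL` to skip purity (all `NA`). Defaults to the bundled published
#'   values.
#' @return A tibble with columns `sample_id`, `immune_score`, `stroma_score`,
#'   `estimate_score` (= immune + stroma, exactly) and `purity`.
#' @export
score_estimate <- function(expr_data, immune_genes = NULL, stroma_genes = NULL,
                           purity_coef = estimate_purity_coef(), workers = 1L) {
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  reg <- load_registry()
  immune_genes <- immune_genes %||% reg$estimate_immune$up
  stroma_genes <- stroma_genes %||% reg$estimate_stroma$up
  for (nm in c("immune", "stroma")) {
    g <- if (nm == "immune") immune_genes else stroma_genes
    if (length(intersect(g, rownames(mat))) == 0L) {
      abort(paste0("the ", nm, " gene set has no genes in the expression matrix."))
    }
  }

  sc <- score_ssgsea(mat, list(immune_score = immune_genes, stroma_score = stroma_genes),
                     alpha = 0.25, norm = "raw", workers = workers)
  out <- tibble::tibble(
    sample_id = sc$sample_id,
    immune_score = sc$immune_score,
    stroma_score = sc$stroma_score,
    estimate_score = sc$immune_score + sc$stroma_score
  )

  if (is.null(purity_coef)) {
    out$purity <- NA_real_
  } else {
    if (length(purity_coef) != 2L || !all(is.finite(purity_coef))) {
      abort("`purity_coef` must be two finite numbers c(a, b).")
    }
    arg <- purity_coef[[1]] + purity_coef[[2]] * out$estimate_score
    off_branch <- arg < 0 | arg > pi
    purity <- pmin(1, pmax(0, cos(arg)))
    if (any(off_branch)) {
      warn(paste0(sum(off_branch), " sample(s) outside the monotone branch of the ",
                  "purity cosine; purity set to NA for them."))
      purity[off_branch] <- NA_real_
    }
    out$purity <- purity
  }
  class(out) <- unique(c("estimate_tbl", class(out)))
  out
}

#' Published cosine coefficients for the purity mapping
#'
#' Reads `(a, b)` of `purity = cos(a + b * estimate_score)` from the bundled
#' config file, which carries the source DOI.
#'
#' @return A named numeric vector `c(a = ..., b = ...)`.
#' @export
estimate_purity_coef <- function() {
  path <- system.file("signatures", "estimate-purity.yml", package = "sigscore")
  y <- yaml::read_yaml(path)
  c(a = y$a, b = y$b)
}
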