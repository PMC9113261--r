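#' Validate a gene-by-sample expression table
#'
#' Converts a raw expression table into the canonical internal form used by all
#' scoring engines: a numeric matrix with unique gene symbols as row names and
#' unique sample identifiers as column names. Expression values are expected to
#' be already normalized (log-intensities or log-counts); no normalization is
#' performed here.
#'
#' Validation applies, in order:
#' * gene symbols are trimmed of surrounding whitespace and matched
#'   case-sensitively (official HUGO symbols are assumed; no alias mapping);
#' * rows containing any missing or non-finite value are dropped, with a
#'   message reporting how many;
#' * duplicate gene symbols are collapsed by keeping the row with the highest
#'   mean expression (the usual probe-collapse convention);
#' * duplicate sample identifiers are an error.
#'
#' Row order of retained genes and column order of samples are preserved, and
#' the function is idempotent: validating an already validated matrix returns
#' it unchanged.
#'
#' @param expr_data A numeric matrix with gene symbols as row names, or a data
#'   frame with one gene-symbol column (see `gene_col`) and one numeric column
#'   per sample.
#' @param gene_col For data-frame input, the name of the gene-symbol column.
#'   Defaults to the first non-numeric column (or the first column if all are
#'   numeric-looking but the first is character).
#' @param quiet Suppress informational messages about dropped rows.
#'
#' @return A numeric matrix, genes in rows and samples in columns.
#' @examples
#' m <- matrix(rnorm(6, 6), 3, 2, dimnames = list(c("TP53", "EGFR", "MYC"), c("s1", "s2")))
#' as_expr_matrix(m)
#' @export
as_expr_matrix <- function(expr_data, gene_col = NULL, quiet = FALSE) {
  if (is.data.frame(expr_data)) {
    if (ncol(expr_data) < 2L) {
      abort("expression table needs a gene column plus at least one sample column.")
    }
    if (is.null(gene_col)) {
      is_chr <- vapply(expr_data, function(x) is.character(x) || is.factor(x), logical(1))
      gene_col <- if (any(is_chr)) names(expr_data)[which(is_chr)[1]] else names(expr_data)[1]
    }
    if (gene_col %!in% names(expr_data)) {
      abort(paste0("gene column '", gene_col, "' not found in expression table."))
    }
    genes <- as.character(expr_data[[gene_col]])
    vals <- expr_data[setdiff(names(expr_data), gene_col)]
    not_num <- !vapply(vals, is.numeric, logical(1))
    if (any(not_num)) {
      abort(paste0("non-numeric sample column(s): ",
                   paste(names(vals)[not_num], collapse = ", ")))
    }
    mat <- as.matrix(vals)
    rownames(mat) <- genes
  } else if (is.matrix(expr_data)) {
    if (nrow(expr_data) == 0L || ncol(expr_data) == 0L) {
      abort("expression table is empty: need at least one gene and one sample.")
    }
    if (!is.numeric(expr_data)) abort("expression matrix must be numeric.")
    if (is.null(rownames(expr_data))) abort("expression matrix must have gene symbols as row names.")
    mat <- expr_data
  } else {
    abort("`expr_data` must be a matrix or a data frame.")
  }

  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    abort("expression table is empty: need at least one gene and one sample.")
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("sample", seq_len(ncol(mat)))
  }
  if (anyDuplicated(colnames(mat))) {
    dups <- unique(colnames(mat)[duplicated(colnames(mat))])
    abort(paste0("duplicate sample identifiers: ", paste(dups, collapse = ", ")))
  }

  rownames(mat) <- trimws(rownames(mat))
  if (any(rownames(mat) == "")) abort("empty gene symbol after trimming whitespace.")

  bad_row <- !apply(mat, 1L, function(x) all(is.finite(x)))
  if (any(bad_row)) {
    if (!quiet) {
      inform(paste0("dropped ", sum(bad_row),
                    " gene row(s) containing missing or non-finite values."))
    }
    mat <- mat[!bad_row, , drop = FALSE]
  }
  if (nrow(mat) == 0L) {
    abort("all gene rows were dropped during validation; no finite data left.")
  }

  if (anyDuplicated(rownames(mat))) {
    means <- rowMeans(mat)
    ord <- order(-means)            # highest-mean row wins within a symbol
    keep_first <- ord[!duplicated(rownames(mat)[ord])]
    keep <- sort(keep_first)        # restore original row order
    n_dropped <- nrow(mat) - length(keep)
    if (!quiet) {
      inform(paste0("collapsed ", n_dropped,
                    " duplicate gene row(s), keeping the highest-mean row per symbol."))
    }
    mat <- mat[keep, , drop = FALSE]
  }

  mat
}
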