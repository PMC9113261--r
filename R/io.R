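#' Read a gene-by-sample expression table from delimited text
#'
#' Reads a tab- or comma-separated table with a gene-symbol column and one
#' numeric column per sample, then validates it with [as_expr_matrix()]
#' (duplicate-symbol collapse, missing-value row drops, duplicate-sample
#' error). The matrix dimensions are reported on load.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; default guesses `","` for `.csv`, otherwise
#'   tab.
#' @param gene_col Name of the gene-symbol column; defaults to the first
#'   column.
#' @param quiet Suppress informational messages.
#' @return A validated numeric matrix, genes in rows and samples in columns.
#' @export
read_expression <- function(path, delim = NULL, gene_col = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      name_repair = "minimal", progress = FALSE),
    error = function(e) abort(paste0("cannot parse '", path, "': ", conditionMessage(e)))
  )
  if (ncol(df) < 2L) {
    abort(paste0("'", path, "': expected a gene column plus at least one sample ",
                 "column with delimiter '", delim, "'."))
  }
  if (anyDuplicated(names(df))) {
    dups <- unique(names(df)[duplicated(names(df))])
    abort(paste0("'", path, "': duplicated sample header(s): ",
                 paste(dups, collapse = ", ")))
  }
  gene_col <- gene_col %||% names(df)[1]
  df[[gene_col]] <- as.character(df[[gene_col]])
  mat <- as_expr_matrix(df, gene_col = gene_col, quiet = quiet)
  if (!quiet) inform(paste0("read ", nrow(mat), " genes x ", ncol(mat),
                            " samples from '", path, "'."))
  mat
}

#' Write a tidy score table to delimited text
#'
#' @param scores A score tibble (`sample_id` plus score columns), as returned
#'   by [sig_score()] and the engines.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @param layout `"wide"` (one row per sample, one column per signature,
#'   the tidy contract) or `"long"` (`sample_id`, `signature_id`, `score`
#'   rows). Missing scores are written as the literal `NA` token; numbers are
#'   written at full (round-trip) precision.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!is.data.frame(scores) || "sample_id" %!in% names(scores)) {
    abort("`scores` must be a data frame with a `sample_id` column.")
  }
  out <- if (layout == "long") scores_long(scores) else scores
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the file.
#' @param layout Layout the file was written with; `"long"` input is pivoted
#'   back to the wide tidy contract.
#' @return A wide score tibble.
#' @export
read_scores <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (layout == "long") df <- scores_wide(df)
  new_score_tbl(tibble::as_tibble(df))
}

#' Pivot a wide score table to long form
#'
#' @param scores Wide score tibble (`sample_id` + score columns).
#' @return Tibble with columns `sample_id`, `signature_id`, `score`.
#' @export
scores_long <- function(scores) {
  tidyr::pivot_longer(tibble::as_tibble(scores), -"sample_id",
                      names_to = "signature_id", values_to = "score")
}

#' Pivot a long score table back to the wide tidy contract
#'
#' Inverse of [scores_long()]: `scores_wide(scores_long(x))` reproduces `x`.
#'
#' @param scores Long tibble with columns `sample_id`, `signature_id`, `score`.
#' @return Wide score tibble.
#' @export
scores_wide <- function(scores) {
  need <- c("sample_id", "signature_id", "score")
  if (!all(need %in% names(scores))) {
    abort("long score table needs columns sample_id, signature_id, score.")
  }
  out <- tidyr::pivot_wider(scores, names_from = "signature_id",
                            values_from = "score")
  new_score_tbl(out)
}
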