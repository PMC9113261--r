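#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line with
#' fields name, description, then one or more gene symbols. Blank lines are
#' skipped; duplicated genes within a set are removed keeping the first
#' occurrence; a line with fewer than three fields is an error citing the
#' line number.
#'
#' @param path Path to a GMT file.
#' @return A named list of character gene vectors; each element carries the
#'   set description in its `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) abort(paste0("GMT file is empty: ", path))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      abort(paste0("GMT line ", i, ": expected name, description and at least ",
                   "one gene (tab-separated), got ", length(fields), " field(s)."))
    }
    name <- fields[[1]]
    if (!nzchar(name)) abort(paste0("GMT line ", i, ": empty set name."))
    genes <- unique(fields[-(1:2)])
    attr(genes, "description") <- fields[[2]]
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character gene vectors (descriptions taken from
#'   each element's `"description"` attribute, empty otherwise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of gene vectors.")
  }
  lines <- purrr::imap_chr(sets, function(genes, name) {
    desc <- attr(genes, "description") %||% ""
    paste(c(name, desc, unique(as.character(genes))), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
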