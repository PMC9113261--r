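# Bundled signature registry: one structured-text (YAML) file per signature
# under inst/signatures/, validated at load and cached per session.

read_signature_file <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$id)) return(NULL)  # auxiliary config files carry no id
  coefs <- if (!is.null(y$coefficients)) unlist(y$coefficients)
  sig <- new_signature(
    id = y$id,
    up = if (!is.null(y$up)) unlist(y$up) else unique(unlist(purrr::map(y$markers, "genes"))),
    down = if (!is.null(y$down)) unlist(y$down) else character(),
    coefficients = coefs,
    method = y$method %||% "mean",
    keywords = unlist(y$keywords) %||% character(),
    doi = y$doi %||% "",
    description = trimws(y$description %||% "")
  )
  sig$markers <- y$markers
  sig
}

load_registry <- function() {
  if (!is.null(the$registry)) return(the$registry)
  dir <- system.file("signatures", package = "sigscore")
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  sigs <- purrr::compact(purrr::map(files, read_signature_file))
  names(sigs) <- purrr::map_chr(sigs, "id")
  if (anyDuplicated(names(sigs))) abort("duplicate signature ids in bundled registry.")
  the$registry <- sigs[order(names(sigs))]
  the$registry
}

registry_keywords <- function(reg = load_registry()) {
  sort(unique(c(names(reg), tolower(unlist(purrr::map(reg, "keywords"))))))
}

# Select registry signatures by keyword. Matching is substring and
# case-insensitive against the id and keywords (exact = TRUE for literal
# whole-keyword matches); multiple keywords select the union of their matches.
registry_select <- function(keywords, exact = FALSE) {
  reg <- load_registry()
  if (length(keywords) == 1L && identical(tolower(keywords), "all")) return(reg)
  hit <- purrr::map_lgl(reg, function(s) {
    hay <- tolower(c(s$id, s$keywords))
    any(purrr::map_lgl(tolower(keywords), function(k) {
      if (exact) k %in% hay else any(grepl(k, hay, fixed = TRUE))
    }))
  })
  if (!any(hit)) {
    abort(paste0("no bundled signature matches ",
                 paste0("'", keywords, "'", collapse = ", "),
                 ". Valid keywords include: ",
                 paste(registry_keywords(reg), collapse = ", ")))
  }
  reg[hit]
}

#' List the bundled gene signatures
#'
#' One row per bundled signature, ordered by id: identifier, search keywords,
#' DOI of the original publication, a short description, the original scoring
#' method, and the number of genes.
#'
#' @return A tibble with columns `signature_id`, `keywords`, `doi`,
#'   `description`, `method`, `n_genes`.
#' @examples
#' sig_info()
#' @export
sig_info <- function() {
  reg <- load_registry()
  tibble::tibble(
    signature_id = names(reg),
    keywords = purrr::map_chr(reg, ~ paste(.x$keywords, collapse = ", ")),
    doi = purrr::map_chr(reg, "doi"),
    description = purrr::map_chr(reg, "description"),
    method = purrr::map_chr(reg, "method"),
    n_genes = purrr::map_int(reg, ~ length(union(.x$up, .x$down)))
  )
}

#' Gene lists of bundled signatures
#'
#' @param signatures `"all"` (default) or a character vector of keywords;
#'   matching is substring and case-insensitive against ids and keywords,
#'   and several keywords select the union of their matches.
#' @param exact Require exact (whole-keyword, still case-insensitive) matches.
#' @return A named list, one character vector of HUGO symbols per matched
#'   signature (up and down genes pooled, up first).
#' @examples
#' names(sig_genes("immune"))
#' @export
sig_genes <- function(signatures = "all", exact = FALSE) {
  reg <- registry_select(signatures, exact = exact)
  purrr::map(reg, ~ c(.x$up, .x$down))
}
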