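# Normalization of user-supplied gene sets into the internal signature form.
#
# A signature is a list with fields:
#   id, up (character, non-empty), down (character, possibly empty),
#   coefficients (named numeric or NULL), method (mean | weighted_sum |
#   ssgsea_like | dedicated_estimate | dedicated_cinsarc | dedicated_ips),
#   keywords, doi, description.

new_signature <- function(id, up, down = character(), coefficients = NULL,
                          method = "mean", keywords = character(),
                          doi = "", description = "") {
  up <- unique(trimws(as.character(up)))
  down <- unique(trimws(as.character(down)))
  if (length(up) == 0L) abort(paste0("signature '", id, "': up gene list is empty."))
  overlap <- intersect(up, down)
  if (length(overlap) > 0L) {
    abort(paste0("signature '", id, "': genes in both up and down lists: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  if (identical(method, "weighted_sum")) {
    need <- union(up, down)
    if (is.null(coefficients) || !all(need %in% names(coefficients))) {
      abort(paste0("signature '", id,
                   "': weighted_sum requires a coefficient for every signature gene."))
    }
  }
  list(id = id, up = up, down = down,
       coefficients = coefficients, method = method,
       keywords = keywords, doi = doi, description = description)
}

# Accepts: a named list whose elements are character vectors (undirected sets)
# or lists with `up` and optional `down` / `coefficients`; or a single
# character vector is rejected (sets must be named so score columns have names).
as_sig_list <- function(signatures) {
  if (!is.list(signatures) || is.data.frame(signatures)) {
    abort("custom signatures must be a *named list* of gene sets.")
  }
  if (length(signatures) == 0L) abort("empty signature list.")
  nms <- names(signatures)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("every custom gene set needs a unique non-empty name.")
  }
  purrr::imap(signatures, function(s, id) {
    if (is.character(s)) return(new_signature(id, up = s))
    if (is.list(s) && !is.null(s$id) && !is.null(s$up) && !is.null(s$method)) {
      return(s)  # already internal form
    }
    if (is.list(s)) {
      return(new_signature(id,
                           up = s$up %||% s$genes %||% abort(paste0("set '", id, "': no `up` genes.")),
                           down = s$down %||% character(),
                           coefficients = unlist(s$coefficients),
                           method = s$method %||% "mean"))
    }
    abort(paste0("set '", id, "' must be a character vector or a list(up=, down=)."))
  })
}

# Intersect one signature with the genes of a matrix; used by every engine.
intersect_sig <- function(sig, genes) {
  list(up = intersect(sig$up, genes), down = intersect(sig$down, genes))
}
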