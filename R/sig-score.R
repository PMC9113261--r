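#' Compute signature scores: the main entry point
#'
#' `sig_score()` dispatches an expression matrix and a choice of signatures to
#' the appropriate scoring procedure and returns a tidy tibble with one row
#' per sample, a `sample_id` column and one column per signature.
#'
#' Dispatch rules:
#' * `signatures` as `"all"` or a keyword vector selects bundled registry
#'   signatures; with the default `method = "original"` each is scored by its
#'   own published procedure (mean or coefficient-weighted sum; signatures
#'   whose original procedure is ssGSEA-like are scored with raw ssGSEA,
#'   alpha = 0.25). Registry signatures with dedicated scorers (ESTIMATE-,
#'   CINSARC- and Immunophenoscore-style) are excluded here with a message
#'   pointing to [score_estimate()], [classify_cinsarc()] and [score_ips()].
#' * `method` set to `"zscore"`, `"ssgsea"` or `"singscore"` scores every
#'   selected signature with that single-sample enrichment engine instead.
#' * `signatures` as a named list of custom gene sets is scored with the
#'   requested engine; `method = "original"` is not meaningful for custom sets
#'   and raises an error. If `method` is not given, custom sets get raw
#'   ssGSEA scores by default.
#'
#' @inheritParams score_zscore
#' @param signatures `"all"`, a character vector of registry keywords, or a
#'   named list of custom gene sets (character vectors or `list(up=, down=)`).
#' @param method `NULL` (default: `"original"` for registry selections, raw
#'   `"ssgsea"` for custom sets) or one of `"original"`, `"zscore"`,
#'   `"ssgsea"`, `"singscore"`.
#' @param alpha,norm ssGSEA options, see [score_ssgsea()].
#' @param center,undirected singscore options, see [score_singscore()].
#' @param tie_rule Rank tie-handling for the rank-based engines.
#' @param exact Exact registry keyword matching, see [sig_genes()].
#' @return A tibble (`score_tbl`): `sample_id` plus one numeric column per
#'   scored signature.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200, 6), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' sig_score(m, list(setA = paste0("g", 1:5), setB = paste0("g", 6:12)),
#'           method = "zscore")
#' @export
sig_score <- function(expr_data, signatures = "all", method = NULL,
                      alpha = 0.25, norm = c("raw", "separate", "all"),
                      center = TRUE, undirected = c("raw_rank", "abs_median_centered"),
                      tie_rule = c("average", "min", "max"),
                      exact = FALSE, workers = 1L) {
  norm <- match.arg(norm)
  undirected <- match.arg(undirected)
  tie_rule <- match.arg(tie_rule)
  custom <- !is.character(signatures)

  if (is.null(method)) method <- if (custom) "ssgsea" else "original"
  method <- match.arg(method, c("original", "zscore", "ssgsea", "singscore"))

  if (custom) {
    if (method == "original") {
      abort("method = 'original' is only defined for bundled registry signatures; pick zscore, ssgsea or singscore for custom gene sets.")
    }
    sigs <- as_sig_list(signatures)
  } else {
    sigs <- registry_select(signatures, exact = exact)
  }

  if (method == "zscore") {
    return(score_zscore(expr_data, sigs, workers = workers))
  }
  if (method == "ssgsea") {
    return(score_ssgsea(expr_data, sigs, alpha = alpha, norm = norm,
                        tie_rule = tie_rule, workers = workers))
  }
  if (method == "singscore") {
    return(score_singscore(expr_data, sigs, center = center,
                           undirected = undirected, tie_rule = tie_rule,
                           workers = workers))
  }

  # method == "original" on registry signatures
  dedicated <- purrr::map_lgl(sigs, ~ startsWith(.x$method, "dedicated"))
  if (any(dedicated)) {
    inform(paste0("excluding signature(s) with dedicated scorers: ",
                  paste(names(sigs)[dedicated], collapse = ", "),
                  " (see score_estimate(), classify_cinsarc(), score_ips())."))
    sigs <- sigs[!dedicated]
  }
  if (length(sigs) == 0L) {
    abort("all selected signatures require dedicated scorers; nothing to score with method = 'original'.")
  }

  ssgsea_like <- purrr::map_lgl(sigs, ~ .x$method == "ssgsea_like")
  parts <- list()
  if (any(!ssgsea_like)) {
    parts <- c(parts, list(score_original(expr_data, sigs[!ssgsea_like], workers = workers)))
  }
  if (any(ssgsea_like)) {
    parts <- c(parts, list(score_ssgsea(expr_data, sigs[ssgsea_like], alpha = 0.25,
                                        norm = "raw", workers = workers)))
  }
  out <- purrr::reduce(parts, dplyr::left_join, by = "sample_id")
  new_score_tbl(out[c("sample_id", names(sigs))])
}
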