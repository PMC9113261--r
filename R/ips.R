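#' Immunophenoscore-style immune marker aggregation
#'
#' Aggregates per-gene cohort z-scores into immune marker scores, weighted
#' category scores for the four immunophenogram categories (MHC molecules,
#' effector cells EC, suppressor cells SC, checkpoints CP), an aggregate
#' score `az`, and the integer 0-10 score `ips`.
#'
#' Steps per sample: each gene is z-scored across the cohort (sample sd,
#' divisor n - 1; constant genes give z = 0); a marker's score is the mean z
#' of its genes; a category's score is the weighted mean of its markers'
#' scores, `sum(w * s) / sum(|w|)`, so that negatively weighted suppressive
#' and checkpoint markers pull the category down; `az` is the sum of the four
#' category scores; `ips = 0` when `az <= 0`, otherwise
#' `min(10, round(az * 10 / 3))` with half-values rounded away from zero.
#'
#' Markers with none of their genes in the matrix are dropped with a warning;
#' a category losing all its markers is an error naming the category.
#'
#' @inheritParams score_zscore
#' @param config Marker table: a data frame or list of records with fields
#'   `name`, `category` (one of MHC, EC, SC, CP), `weight`, `genes`.
#'   Defaults to the bundled table (a synthetic demonstration stand-in for
#'   the published one; see its registry description).
#' @return A tibble (`ips_tbl`): `sample_id`, one column per marker, the four
#'   category columns `MHC`, `EC`, `SC`, `CP`, `az` and integer `ips`.
#' @export
score_ips <- function(expr_data, config = NULL) {
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  markers <- normalize_ips_config(config %||% load_registry()$immunophenoscore$markers)

  present <- purrr::map(markers, ~ intersect(.x$genes, rownames(mat)))
  keep <- lengths(present) > 0L
  if (any(!keep)) {
    warn(paste0("dropping marker(s) with no genes in the matrix: ",
                paste(purrr::map_chr(markers[!keep], "name"), collapse = ", ")))
  }
  markers <- markers[keep]; present <- present[keep]
  cats <- purrr::map_chr(markers, "category")
  lost <- setdiff(c("MHC", "EC", "SC", "CP"), cats)
  if (length(lost) > 0L) {
    abort(paste0("no marker genes present for category: ",
                 paste(lost, collapse = ", ")))
  }

  mu <- rowMeans(mat)
  sdev <- apply(mat, 1L, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- Inf   # constant genes -> z = 0
  z <- (mat - mu) / sdev

  marker_scores <- purrr::map(present, function(g) colMeans(z[g, , drop = FALSE]))
  names(marker_scores) <- purrr::map_chr(markers, "name")
  weights <- purrr::map_dbl(markers, "weight")

  cat_score <- function(cat) {
    idx <- which(cats == cat)
    w <- weights[idx]
    s <- do.call(rbind, marker_scores[idx])   # markers x samples
    colSums(w * s) / sum(abs(w))
  }
  cat_scores <- purrr::map(stats::setNames(nm = c("MHC", "EC", "SC", "CP")), cat_score)
  az <- Reduce(`+`, cat_scores)
  ips <- ifelse(az <= 0, 0, pmin(10, round_half_away(az * 10 / 3)))

  out <- tibble::tibble(sample_id = colnames(mat))
  for (nm in names(marker_scores)) out[[nm]] <- unname(marker_scores[[nm]])
  for (nm in names(cat_scores)) out[[nm]] <- unname(cat_scores[[nm]])
  out$az <- unname(az)
  out$ips <- as.integer(ips)
  class(out) <- unique(c("ips_tbl", class(out)))
  out
}

normalize_ips_config <- function(config) {
  if (is.data.frame(config)) {
    config <- purrr::pmap(config, function(name, category, weight, genes, ...) {
      list(name = name, category = category, weight = weight, genes = unlist(genes))
    })
  }
  if (!is.list(config) || length(config) == 0L) abort("empty or invalid IPS marker config.")
  purrr::map(config, function(m) {
    if (is.null(m$name) || is.null(m$category) || is.null(m$weight) || length(m$genes) == 0L) {
      abort("every IPS marker needs `name`, `category`, `weight` and a non-empty `genes` list.")
    }
    if (m$category %!in% c("MHC", "EC", "SC", "CP")) {
      abort(paste0("marker '", m$name, "': category must be one of MHC, EC, SC, CP."))
    }
    list(name = m$name, category = m$category,
         weight = as.numeric(m$weight), genes = unlist(m$genes))
  })
}
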