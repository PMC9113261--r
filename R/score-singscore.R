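#' Rank-based (singscore-style) signature scores
#'
#' Scores a signature in one sample as the normalized mean rank of its genes.
#' For an up set of size n in a sample of N genes the attainable mean rank
#' spans \[(n+1)/2, (2N-n+1)/2\]; the up-score is the mean rank rescaled onto
#' \[0, 1\] over that span. Down sets are scored the same way on reversed ranks
#' (N + 1 - rank), so that lowly expressed down genes score high. With
#' `center = TRUE` (default) each directional score is shifted by -0.5 onto
#' \[-0.5, 0.5\]; a bidirectional total is the sum of the two directional
#' scores.
#'
#' Undirected sets are treated as up sets by default (`undirected =
#' "raw_rank"`); with `"abs_median_centered"` genes are instead ranked by the
#' absolute deviation of expression from the sample median, which rewards
#' genes that are extreme in either direction.
#'
#' @inheritParams score_ssgsea
#' @param center Subtract 0.5 from each directional score (default `TRUE`).
#' @param undirected How to score sets without a down list: `"raw_rank"`
#'   (default) or `"abs_median_centered"`.
#' @return A tibble, one row per sample, one score column per signature.
#' @export
score_singscore <- function(expr_data, signatures, center = TRUE,
                            undirected = c("raw_rank", "abs_median_centered"),
                            tie_rule = c("average", "min", "max"),
                            workers = 1L) {
  undirected <- match.arg(undirected)
  tie_rule <- match.arg(tie_rule)
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  sigs <- as_sig_list(signatures)
  n_genes <- nrow(mat)

  present <- purrr::map(sigs, intersect_sig, genes = rownames(mat))
  sizes <- purrr::map(present, ~ c(up = length(.x$up), down = length(.x$down)))
  spanning <- purrr::map_lgl(sizes, ~ any(.x == n_genes))
  if (any(spanning)) {
    abort(paste0("signature(s) spanning every gene in the matrix (score undefined): ",
                 paste(names(sigs)[spanning], collapse = ", ")))
  }
  empty_up <- purrr::map_lgl(present, ~ length(.x$up) == 0L)
  if (any(empty_up)) {
    warn(paste0("no up genes present for signature(s): ",
                paste(names(sigs)[empty_up], collapse = ", "), "; scores set to NA."))
  }
  lost_down <- purrr::map2_lgl(sigs, present,
                               ~ length(.x$down) > 0L && length(.y$down) == 0L)
  if (any(lost_down)) {
    warn(paste0("down gene list fully absent for signature(s): ",
                paste(names(sigs)[lost_down], collapse = ", "),
                "; scored as up-only."))
  }

  dir_score <- function(mean_rank, n, N) {
    r_min <- (n + 1) / 2
    r_max <- (2 * N - n + 1) / 2
    (mean_rank - r_min) / (r_max - r_min)
  }

  score_one <- function(x) {
    r <- rank_sample(x, tie_rule)
    r_abs <- if (undirected == "abs_median_centered") {
      rank_sample(abs(x - median(x)), tie_rule)
    } else NULL
    vapply(present, function(p) {
      if (length(p$up) == 0L) return(NA_real_)
      bidir <- length(p$down) > 0L
      r_up <- if (!bidir && !is.null(r_abs)) r_abs else r
      up <- dir_score(mean(r_up[p$up]), length(p$up), n_genes)
      if (center) up <- up - 0.5
      if (!bidir) return(up)
      down <- dir_score(mean(n_genes + 1 - r[p$down]), length(p$down), n_genes)
      if (center) down <- down - 0.5
      up + down
    }, numeric(1))
  }

  scores_to_tbl(per_sample_apply(mat, score_one, workers), names(sigs))
}
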