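#' Single-sample GSEA (ssGSEA) signature scores
#'
#' For each sample, genes are ranked by expression (1 = lowest) and walked in
#' order of decreasing rank. Along that walk two empirical distributions are
#' accumulated: the in-set distribution, weighted by rank^alpha and normalized
#' by the total in-set weight, and the uniform out-of-set distribution. The
#' enrichment score is the sum over all walk positions of their difference:
#'
#' \deqn{ES = \sum_{i=1}^{N} \left( P_{in}(i) - P_{out}(i) \right)}
#'
#' Up and down gene lists are pooled (the statistic is undirected). Scores are
#' returned raw by default; `norm = "separate"` rescales each signature column
#' by its own score range (max - min), `norm = "all"` rescales every column by
#' the global range across all requested signatures — with either option the
#' scores become cohort- and signature-set-dependent, so raw is the default.
#'
#' @inheritParams score_zscore
#' @param alpha Exponent of the rank weight in the running sum; 0 weights all
#'   in-set genes equally. Default 0.25.
#' @param norm `"raw"` (default), `"separate"` or `"all"`.
#' @param tie_rule Tie-handling for within-sample ranks, see [rank_sample()].
#' @return A tibble, one row per sample, one score column per signature.
#' @examples
#' m <- matrix(c(3, 2, 1, 1, 2, 3), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' score_ssgsea(m, list(top = "g1"), alpha = 1)
#' @export
score_ssgsea <- function(expr_data, signatures, alpha = 0.25,
                         norm = c("raw", "separate", "all"),
                         tie_rule = c("average", "min", "max"),
                         workers = 1L) {
  norm <- match.arg(norm)
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort("`alpha` must be a single finite non-negative number.")
  }
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  sigs <- as_sig_list(signatures)
  n_genes <- nrow(mat)

  members <- purrr::map(sigs, function(s) intersect(union(s$up, s$down), rownames(mat)))
  full <- purrr::map_lgl(members, ~ length(.x) == n_genes)
  if (any(full)) {
    abort(paste0("signature(s) covering every gene in the matrix (out-set empty): ",
                 paste(names(sigs)[full], collapse = ", ")))
  }
  empty <- purrr::map_lgl(members, ~ length(.x) == 0L)
  if (any(empty)) {
    warn(paste0("no genes present for signature(s): ",
                paste(names(sigs)[empty], collapse = ", "), "; scores set to NA."))
  }
  in_set <- purrr::map(members, function(g) rownames(mat) %in% g)

  score_one <- function(x) {
    r <- rank_sample(x, tie_rule)
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    vapply(seq_along(sigs), function(k) {
      memb <- in_set[[k]][ord]
      m <- sum(memb)
      if (m == 0L) return(NA_real_)
      w_in <- w * memb
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!memb) / (n_genes - m)
      sum(p_in - p_out)
    }, numeric(1))
  }

  raw <- per_sample_apply(mat, score_one, workers)
  raw <- lapply(raw, `names<-`, names(sigs))
  out <- scores_to_tbl(raw, names(sigs))
  normalize_scores(out, norm)
}

# Range normalization of a score table, shared with the dispatcher.
normalize_scores <- function(scores, norm) {
  if (norm == "raw") return(scores)
  cols <- setdiff(names(scores), "sample_id")
  if (norm == "separate") {
    for (cl in cols) {
      rng <- diff(range(scores[[cl]], na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        abort(paste0("cannot normalize signature '", cl,
                     "': zero score range in this cohort."))
      }
      scores[[cl]] <- scores[[cl]] / rng
    }
  } else { # all
    rng <- diff(range(unlist(scores[cols]), na.rm = TRUE))
    if (!is.finite(rng) || rng == 0) {
      abort("cannot normalize: zero global score range across all signatures in this cohort.")
    }
    for (cl in cols) scores[[cl]] <- scores[[cl]] / rng
  }
  scores
}
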