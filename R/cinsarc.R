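#' CINSARC-style nearest-centroid risk classification
#'
#' Classifies each sample as low risk (C1) or high risk (C2) by
#' leave-one-out nearest-centroid distance in standardized signature-gene
#' space, trained on a per-sample binary distant-metastasis status.
#'
#' The procedure: restrict the matrix to the signature genes present;
#' standardize each gene across samples (mean 0, sd 1); for every sample,
#' recompute the per-gene mean centroid of the no-metastasis (status 0) and
#' metastasis (status 1) groups with that sample held out of its own group;
#' measure the distance from the sample to both centroids; assign C1 when the
#' sample is strictly closer to the no-metastasis centroid, C2 otherwise
#' (ties go to C2, the high-risk call).
#'
#' @inheritParams score_zscore
#' @param labels Distant-metastasis status: a data frame with columns
#'   `sample_id` and `status` (0 = no metastasis, 1 = metastasis), or a named
#'   0/1 vector. Every sample in the matrix must be covered and each class
#'   needs at least two samples.
#' @param genes Signature gene list; defaults to the bundled registry entry
#'   (a synthetic demonstration stand-in for the published 67-gene list).
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation to the centroid).
#' @param restandardize Recompute the gene standardization within every
#'   leave-one-out fold (excluding the held-out sample) instead of once on
#'   the full cohort. Default `FALSE`.
#' @return A tibble (`cinsarc_tbl`) with columns `sample_id`, `risk_class`
#'   (`"C1"`/`"C2"`), `dist_lowrisk`, `dist_highrisk`.
#' @export
classify_cinsarc <- function(expr_data, labels, genes = NULL,
                             metric = c("euclidean", "correlation"),
                             restandardize = FALSE) {
  metric <- match.arg(metric)
  mat <- as_expr_matrix(expr_data, quiet = TRUE)
  genes <- genes %||% load_registry()$cinsarc$up

  status <- normalize_labels(labels, colnames(mat))
  if (sum(status == 0) < 2L || sum(status == 1) < 2L) {
    abort("need at least 2 samples in each metastasis class.")
  }

  pres <- intersect(genes, rownames(mat))
  if (length(pres) == 0L) abort("no signature genes present in the expression matrix.")
  sub <- mat[pres, , drop = FALSE]

  standardize <- function(m) {
    s <- apply(m, 1L, sd)
    s[s == 0 | !is.finite(s)] <- 1
    (m - rowMeans(m)) / s
  }
  zs <- standardize(sub)

  dist_to <- function(x, centroid) {
    if (metric == "euclidean") sqrt(sum((x - centroid)^2))
    else 1 - cor(x, centroid)
  }

  n <- ncol(zs)
  d0 <- numeric(n); d1 <- numeric(n)
  for (i in seq_len(n)) {
    zi <- if (restandardize) standardize(sub[, -i, drop = FALSE]) else zs[, -i, drop = FALSE]
    st <- status[-i]
    if (sum(st == 0) == 0L || sum(st == 1) == 0L) {
      abort("a metastasis class is emptied by leave-one-out; cannot form centroids.")
    }
    c0 <- rowMeans(zi[, st == 0, drop = FALSE])
    c1 <- rowMeans(zi[, st == 1, drop = FALSE])
    x <- if (restandardize) {
      mu <- rowMeans(sub[, -i, drop = FALSE])
      s <- apply(sub[, -i, drop = FALSE], 1L, sd)
      s[s == 0 | !is.finite(s)] <- 1
      (sub[, i] - mu) / s
    } else zs[, i]
    d0[i] <- dist_to(x, c0)
    d1[i] <- dist_to(x, c1)
  }

  out <- tibble::tibble(
    sample_id = colnames(zs),
    risk_class = ifelse(d0 < d1, "C1", "C2"),
    dist_lowrisk = d0,
    dist_highrisk = d1
  )
  class(out) <- unique(c("cinsarc_tbl", class(out)))
  out
}

# Labels as data frame (sample_id, status) or named vector -> 0/1 vector
# aligned with `samples`, erroring on gaps or values outside {0, 1}.
normalize_labels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "status") %in% names(labels))) {
      abort("label table needs columns `sample_id` and `status`.")
    }
    v <- stats::setNames(labels$status, labels$sample_id)
  } else if (!is.null(names(labels))) {
    v <- labels
  } else {
    abort("`labels` must be a data frame (sample_id, status) or a named vector.")
  }
  miss <- setdiff(samples, names(v))
  if (length(miss) > 0L) {
    abort(paste0("missing metastasis label for sample(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  v <- as.numeric(v[samples])
  if (!all(v %in% c(0, 1))) abort("metastasis status must be coded 0/1.")
  v
}
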