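# Internal helpers shared across modules.

# Evaluate `code` with a locally seeded RNG, leaving the caller's random state
# untouched. All simulator randomness flows through this, so there is no
# global-state coupling between calls.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Split indices 1..n into at most `k` contiguous chunks, preserving order.
chunk_indices <- function(n, k) {
  k <- max(1L, min(as.integer(k), n))
  size <- ceiling(n / k)
  unname(split(seq_len(n), ceiling(seq_len(n) / size)))
}

# Apply `fun` to each column (sample) of `mat`, optionally forking over
# `workers` processes. Results are reassembled in column order, so the output
# is identical whatever `workers` is. `fun` receives a named numeric vector.
per_sample_apply <- function(mat, fun, workers = 1L) {
  stopifnot(is.matrix(mat))
  run_chunk <- function(idx) {
    lapply(idx, function(j) fun(mat[, j]))
  }
  chunks <- chunk_indices(ncol(mat), workers)
  if (workers > 1L && length(chunks) > 1L) {
    res <- parallel::mclapply(chunks, run_chunk, mc.cores = length(chunks))
    bad <- vapply(res, inherits, logical(1), "try-error")
    if (any(bad)) abort(paste("parallel worker failed:", res[[which(bad)[1]]]))
  } else {
    res <- lapply(chunks, run_chunk)
  }
  out <- unlist(res, recursive = FALSE, use.names = FALSE)
  names(out) <- colnames(mat)
  out
}

# Assemble per-sample score lists (sample -> named vector of signature scores)
# into the tidy one-row-per-sample table.
scores_to_tbl <- function(sample_scores, sig_ids) {
  rows <- lapply(sample_scores, function(s) as.list(s[sig_ids]))
  out <- dplyr::bind_rows(rows)
  names(out) <- sig_ids
  out <- dplyr::bind_cols(tibble::tibble(sample_id = names(sample_scores)), out)
  new_score_tbl(out)
}

new_score_tbl <- function(x) {
  class(x) <- unique(c("score_tbl", class(tibble::as_tibble(x))))
  x
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%!in%` <- function(x, table) !(x %in% table)
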