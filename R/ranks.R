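#' Rank the expression values of one sample
#'
#' Ranks ascend with expression: 1 is the lowest value, N the highest. Ties are
#' resolved according to `tie_rule`; with the default `"average"` the rank sum
#' is always N(N+1)/2, which the rank-based engines (ssGSEA, singscore) rely
#' on. Ranks depend only on the ordering of values within the sample, never on
#' their scale.
#'
#' @param values Numeric vector of expression values for one sample (length
#'   at least 2, all finite).
#' @param tie_rule One of `"average"`, `"min"`, `"max"`.
#' @return A numeric rank vector with the names of `values`.
#' @examples
#' rank_sample(c(g1 = 5, g2 = 1, g3 = 3))
#' @export
rank_sample <- function(values, tie_rule = c("average", "min", "max")) {
  tie_rule <- match.arg(tie_rule)
  if (length(values) < 2L) abort("need at least 2 values to rank a sample.")
  if (!all(is.finite(values))) abort("cannot rank non-finite expression values.")
  r <- rank(values, ties.method = tie_rule)
  names(r) <- names(values)
  r
}
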