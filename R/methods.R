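# broom-style and ggplot2 methods for the result tibbles.

#' @export
tidy.score_tbl <- function(x, ...) scores_long(x)

#' @export
glance.score_tbl <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x), n_signatures = ncol(x) - 1L,
                 n_missing_scores = sum(is.na(as.matrix(x[-1]))))
}

#' Heatmap of a tidy score table
#'
#' Samples on the x axis, signatures on the y axis, score as fill. Scores of
#' different signatures are on their own scales, so compare within rows.
#'
#' @param object A score tibble from [sig_score()] or a scoring engine.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.score_tbl <- function(object, ...) {
  ggplot2::ggplot(scores_long(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$signature_id,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "sample", y = "signature", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.score_tbl
#' @param scores A score tibble.
#' @export
plot_scores <- function(scores, ...) autoplot(new_score_tbl(scores), ...)

#' @export
tidy.sig_coverage <- function(x, ...) {
  tidyr::unnest(dplyr::select(x, "signature_id", "missing_genes"),
                cols = "missing_genes", keep_empty = FALSE) |>
    dplyr::rename(gene = "missing_genes")
}

#' @export
glance.sig_coverage <- function(x, ...) {
  tibble::tibble(n_signatures = nrow(x),
                 mean_frac_present = mean(x$frac_present),
                 n_fully_covered = sum(x$frac_present == 1))
}

#' Coverage barplot
#'
#' @param object A coverage report from [check_sig()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sig_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frac_present,
                                       y = stats::reorder(.data$signature_id, .data$frac_present))) +
    ggplot2::geom_col() +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "fraction of signature genes present", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.cinsarc_tbl <- function(x, ...) {
  tidyr::pivot_longer(x, c("dist_lowrisk", "dist_highrisk"),
                      names_to = "centroid", values_to = "distance",
                      names_prefix = "dist_")
}

#' @export
glance.cinsarc_tbl <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_c1 = sum(x$risk_class == "C1"),
                 n_c2 = sum(x$risk_class == "C2"))
}

#' Centroid-distance plot for a risk classification
#'
#' Each sample plotted by its distance to the low-risk and high-risk
#' centroids; the diagonal is the decision boundary.
#'
#' @param object A classification tibble from [classify_cinsarc()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cinsarc_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dist_lowrisk,
                                       y = .data$dist_highrisk,
                                       colour = .data$risk_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance to low-risk centroid",
                  y = "distance to high-risk centroid", colour = "class") +
    ggplot2::theme_minimal()
}

#' @export
glance.estimate_tbl <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 mean_estimate = mean(x$estimate_score),
                 mean_purity = mean(x$purity, na.rm = TRUE))
}

#' Purity against combined infiltration score
#'
#' @param object A result tibble from [score_estimate()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.estimate_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate_score, y = .data$purity)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "combined (immune + stroma) score", y = "tumor purity") +
    ggplot2::theme_minimal()
}

#' @export
glance.ips_tbl <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x), mean_az = mean(x$az),
                 median_ips = stats::median(x$ips))
}

#' Immunophenoscore distribution
#'
#' @param object A result tibble from [score_ips()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ips_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$ips, levels = 0:10))) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "immunophenoscore (0-10)", y = "samples") +
    ggplot2::theme_minimal()
}
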