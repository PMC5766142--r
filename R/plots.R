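#' Manhattan-style plot of cluster-level methylation tests
#'
#' @param object A `dmr_results` tibble.
#' @param ... Unused.
#' @return A ggplot: cluster midpoint vs -log10 raw p, surviving calls
#'   highlighted.
#' @export
autoplot.dmr_results <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_raw)) |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2,
                  status = dplyr::case_when(
                    .data$called & !.data$baseline_shared &
                      !.data$blacklisted ~ "called",
                    .data$called ~ "filtered",
                    TRUE ~ "not called"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6,
                                   y = -log10(.data$p_raw),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(called = "#d62728",
                                            filtered = "#ff9896",
                                            `not called` = "grey50")) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  colour = NULL,
                  title = "Cluster-level weighted beta-regression tests")
}

#' Bar chart of the genomic distribution of DMRs
#'
#' @param distribution Output of [genomic_distribution_summary()].
#' @return A ggplot of counts per category, faceted by axis.
#' @export
plot_genomic_distribution <- function(distribution) {
  df <- dplyr::filter(distribution, .data$category != "gene_body")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "DMRs",
                  title = "Genomic context of called DMRs")
}

#' Volcano-style plot of the cis scan
#'
#' @param object A `meqtr_results` tibble.
#' @param ... Unused.
#' @return A ggplot of expression coefficient vs -log10 raw p.
#' @export
autoplot.meqtr_results <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate,
                               y = -log10(.data$p_raw),
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d62728",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "expression coefficient (logit methylation per log2 unit)",
                  y = expression(-log[10](p)), colour = "adjusted p < q",
                  title = "cis methylation-expression associations")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
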