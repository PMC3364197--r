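#' Forest plot of per-SNP odds ratios
#'
#' Joint-model per-allele odds ratios with Wald 95% confidence intervals
#' on a log scale, one row per SNP grouped by gene.
#'
#' @param object A `grs_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grs_model <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$gene_label)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per risk allele (95% CI)", y = NULL,
                  colour = "Gene") +
    ggplot2::theme_minimal()
}

#' Histogram of the GRS distribution by case status
#'
#' Raw study view by default; supplying a `prevalence` reweights the case
#' bars to model a general population with that disease prevalence.
#'
#' @param data A data frame with `status` and a `grs` column.
#' @param prevalence Optional assumed population prevalence in (0,1).
#' @param binwidth Bin width on the GRS scale.
#' @return A ggplot object.
#' @export
plot_grs_distribution <- function(data, prevalence = NULL, binwidth = 0.25) {
  h <- grs_histogram_data(data, prevalence = prevalence, binwidth = binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$weighted_count,
                                  fill = .data$status)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = binwidth) +
    ggplot2::scale_fill_manual(values = c(case = "#c0392b", control = "#2c60a0")) +
    ggplot2::labs(x = "Genetic risk score", fill = NULL,
                  y = if (is.null(prevalence)) "Subjects" else "Weighted subjects") +
    ggplot2::theme_minimal()
}

#' Absolute risk by category across the prevalence grid
#'
#' @param projection Output of [projection_table()].
#' @return A ggplot object.
#' @export
plot_absolute_risk <- function(projection) {
  ggplot2::ggplot(projection,
                  ggplot2::aes(x = .data$category, y = .data$absolute_risk_pct,
                               colour = factor(100 * .data$prevalence),
                               group = .data$prevalence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GRS category", y = "Absolute risk [%]",
                  colour = "Prevalence [%]") +
    ggplot2::theme_minimal()
}
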