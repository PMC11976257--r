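#' Module-by-pattern methylation heatmap
#'
#' Tile plot of beta values for the significant CpGs, rows grouped by CpG
#' module and columns by sample methylation pattern — the standard overview
#' of a fitted subgrouping.
#'
#' @param beta Beta tibble or matrix covering the module CpGs.
#' @param modules Output of [assign_modules()].
#' @param patterns Output of [assign_patterns()].
#' @return A ggplot.
#' @export
plot_module_heatmap <- function(beta, modules, patterns) {
  m <- as_beta_matrix(beta)
  mod <- stats::setNames(as.character(modules$module), modules$cpg_id)
  pat <- stats::setNames(as.character(patterns$pattern), patterns$sample_id)
  cpgs <- modules$cpg_id[order(modules$module)]
  samples <- patterns$sample_id[order(patterns$pattern)]
  df <- as_beta_tbl(m[cpgs, samples, drop = FALSE]) |>
    tidyr::pivot_longer(-"cpg_id", names_to = "sample_id", values_to = "beta") |>
    dplyr::mutate(
      cpg_id = factor(.data$cpg_id, levels = rev(cpgs)),
      sample_id = factor(.data$sample_id, levels = samples),
      module = mod[as.character(.data$cpg_id)],
      pattern = pat[as.character(.data$sample_id)]
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$cpg_id, fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(module ~ pattern, scales = "free", space = "free") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = c(0, 1), name = "beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "samples (by pattern)", y = "CpGs (by module)")
}

#' Per-pattern distribution of a sample statistic
#'
#' Boxplots of a per-sample value (age, epiCMIT score, median methylation,
#' ...) across methylation patterns.
#'
#' @param data Data frame with one row per sample.
#' @param value,pattern Columns (tidy-eval) holding the statistic and the
#'   pattern label.
#' @return A ggplot.
#' @export
plot_pattern_boxes <- function(data, value, pattern) {
  ggplot2::ggplot(data, ggplot2::aes({{ pattern }}, {{ value }},
                                     fill = {{ pattern }})) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::theme_minimal()
}
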