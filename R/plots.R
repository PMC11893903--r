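#' Plot a flow screen ranking
#'
#' Recombination index against significance for every strain, the standard
#' screen overview: hyper-recombinant strains sit right of index 50 at low
#' p.
#'
#' @param object A [score_strains()] result.
#' @param alpha Significance line drawn on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_screen_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_index,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 50, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b",
                                            hypo = "#2980b9",
                                            none = "grey60")) +
    ggplot2::labs(x = "median recombination index",
                  y = expression(-log[10](p)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metagene matrix as a TSS-TES heatmap
#'
#' @param object A [metagene()] result.
#' @param which `"template"` or `"nontemplate"` strand matrix.
#' @param trans Transformation applied to signal for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_matrix <- function(object, which = "template",
                                     trans = function(x) log1p(x), ...) {
  m <- object[[match.arg(which, c("template", "nontemplate"))]]
  df <- tibble::tibble(
    gene = rep(seq_len(nrow(m)), times = ncol(m)),
    column = rep(seq_len(ncol(m)), each = nrow(m)),
    signal = trans(as.vector(m))
  )
  tss <- object$flank_bins + 0.5
  tes <- object$flank_bins + object$body_bins + 0.5
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$gene,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = c(tss, tes), colour = "white",
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "flank | TSS - scaled body - TES | flank",
                  y = "genes (ranked by template-strand density)") +
    ggplot2::theme_minimal()
}

#' Plot per-category hybrid fold-change distributions
#'
#' Tukey box plots of hybrid density fold-changes stratified by expression
#' category.
#'
#' @param fold_changes Tibble with `fold_change` and `category` (see
#'   [stratified_fold_change()]).
#' @return A ggplot.
#' @export
plot_stratified_fold_change <- function(fold_changes) {
  check_columns(fold_changes, c("fold_change", "category"), "fold_changes")
  ggplot2::ggplot(fold_changes,
                  ggplot2::aes(x = .data$category, y = .data$fold_change,
                               fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "hybrid fold-change") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot an OK-seq profile with fitted segment slopes
#'
#' @param object A [sim_okseq()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.okseq_sim <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = .data$signal,
                               group = .data$interval)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "#c0392b") +
    ggplot2::labs(x = "position (bp)", y = "OK-seq signal") +
    ggplot2::theme_minimal()
}
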