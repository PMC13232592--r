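#' Dot plot of risk-gene overrepresentation
#'
#' Rows are cell types, columns disease lists; dot size is the combined
#' overrepresentation score, colour the -log10 hypergeometric p, and an
#' asterisk marks FDR below `fdr_mark`.
#'
#' @param enrichment Tibble from [risk_gene_overrepresentation()].
#' @param fdr_mark Significance mark threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment_grid <- function(enrichment, fdr_mark = 0.05) {
  ggplot(enrichment,
         aes(x = .data$list_name, y = .data$cell_type)) +
    geom_point(aes(size = pmax(.data$score, 0),
                   colour = -log10(pmax(.data$p_value, 1e-300)))) +
    geom_text(data = filter(enrichment, .data$fdr < fdr_mark),
              label = "*", vjust = 0.2, size = 6) +
    facet_wrap(~direction) +
    scale_colour_viridis_c(name = "-log10 p") +
    scale_size_continuous(name = "score") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Heatmap of directionality Pearson residuals
#'
#' One tile per (cell type, evolutionary category x disease direction)
#' cell, coloured by the Pearson residual z-score.
#'
#' @param directionality Result of [directionality_contingency()].
#' @return A ggplot object.
#' @export
plot_directionality <- function(directionality) {
  cells <- list_rbind(imap(directionality$tests, function(tst, ct)
    tidy(tst) |> mutate(cell_type = ct)))
  ggplot(cells, aes(x = paste(.data$row, .data$col, sep = "/"),
                    y = .data$cell_type, fill = .data$residual)) +
    geom_tile() +
    scale_fill_gradient2(name = "Pearson\nresidual") +
    labs(x = "evolutionary category / disease direction", y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Module-score trajectory across age
#'
#' Per-nucleus module and background scores against age (log2 axis when
#' `age_years` is available, age-group otherwise) with a smoothed trend
#' per series.
#'
#' @param trajectory A [module_trajectory_table()] result.
#' @param offset Years added before the log2 age transform (default 0.1).
#' @return A ggplot object.
#' @export
plot_module_trajectory <- function(trajectory, offset = 0.1) {
  scores <- trajectory$scores
  if ("age_years" %in% names(scores)) {
    ggplot(scores, aes(x = log2(.data$age_years + offset), y = .data$score,
                       colour = .data$which)) +
      geom_point(alpha = 0.3, size = 0.6) +
      geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
      labs(x = "age, log2(years + offset)", y = "module score",
           colour = NULL) +
      theme_minimal()
  } else {
    ggplot(scores, aes(x = .data$age_group, y = .data$score,
                       colour = .data$which)) +
      geom_boxplot(outlier.size = 0.5) +
      labs(x = NULL, y = "module score", colour = NULL) +
      theme_minimal()
  }
}

#' @rdname plot_module_trajectory
#' @param object A `module_trajectory`.
#' @param ... Unused.
#' @export
autoplot.module_trajectory <- function(object, ...) {
  plot_module_trajectory(object)
}

#' Bar chart of exclusive intersection sizes
#'
#' The UpSet-style summary of [upset_counts()]: exclusive membership
#' patterns ordered by size.
#'
#' @param upset Tibble from [upset_counts()].
#' @param top_n Keep the largest `top_n` patterns per direction
#'   (default 20).
#' @return A ggplot object.
#' @export
plot_upset_counts <- function(upset, top_n = 20) {
  dat <- upset |>
    group_by(.data$direction) |>
    slice_max(.data$n, n = top_n, with_ties = FALSE) |>
    ungroup()
  ggplot(dat, aes(x = stats::reorder(.data$pattern, -.data$n), y = .data$n)) +
    geom_col() +
    facet_wrap(~direction, scales = "free_x") +
    labs(x = "cell-type membership pattern", y = "exclusive set size") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Scatter of per-TF disease-hit proportions
#'
#' PD-hit proportion against ASD-hit proportion over each TF's retained
#' targets, labelling the top-ranked TFs.
#'
#' @param tf_table Tibble from [per_tf_disease_proportions()].
#' @param label_top Number of top-ranked TFs to label (default 3).
#' @return A ggplot object.
#' @export
plot_tf_disease <- function(tf_table, label_top = 3) {
  ggplot(tf_table, aes(x = .data$prop_pd, y = .data$prop_asd)) +
    geom_point(aes(size = .data$n_targets), alpha = 0.7) +
    geom_text(data = filter(tf_table, .data$rank <= label_top),
              aes(label = .data$tf), vjust = -0.8, size = 3) +
    labs(x = "proportion of targets PD-deregulated",
         y = "proportion of targets ASD-deregulated",
         size = "targets") +
    theme_minimal()
}
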