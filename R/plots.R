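#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   geom_col labs scale_color_manual theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot a t-SNE embedding
#'
#' @param object an `islet_embedding` tibble.
#' @param labels optional named vector (or tibble column) of per-cell
#'   labels to color by (e.g. cell types or cliques).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.islet_embedding <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(labels)) {
    df$label <- as.factor(labels[df$cell_id])
    ggplot(df, aes(x = .data$tsne1, y = .data$tsne2, color = .data$label)) +
      geom_point(size = 0.7) +
      labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$tsne1, y = .data$tsne2)) +
      geom_point(size = 0.7) +
      labs(x = "t-SNE 1", y = "t-SNE 2") +
      theme_minimal()
  }
}

#' MA plot of a differential-expression result
#'
#' Mean normalized expression (log10) against log2 fold change, with genes
#' below the FDR cutoff highlighted.
#'
#' @param object a `de_result` tibble.
#' @param fdr_cut FDR highlight cutoff (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.de_result <- function(object, fdr_cut = 0.05, ...) {
  df <- as_tibble(object) %>%
    filter(!is.na(.data$pvalue)) %>%
    mutate(significant = !is.na(.data$fdr) & .data$fdr < fdr_cut)
  ggplot(df, aes(x = log10(.data$baseMean + 1e-3), y = .data$log2fc,
                 color = .data$significant)) +
    geom_point(size = 0.6) +
    geom_hline(yintercept = 0, linetype = 2) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3")) +
    labs(x = "log10 mean normalized expression", y = "log2 fold change",
         color = sprintf("FDR < %g", fdr_cut)) +
    theme_minimal()
}

#' Normalized enrichment score bar plot
#'
#' @param object a `gsea_result` tibble.
#' @param fdr_cut FDR highlight cutoff (default 0.25).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gsea_result <- function(object, fdr_cut = 0.25, ...) {
  df <- as_tibble(object) %>%
    mutate(significant = !is.na(.data$fdr) & .data$fdr < fdr_cut)
  ggplot(df, aes(x = stats::reorder(.data$set, .data$nes), y = .data$nes,
                 fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "normalized enrichment score",
         fill = sprintf("FDR < %g", fdr_cut)) +
    theme_minimal()
}

#' Running-sum enrichment plot for one gene set
#'
#' @param ranked a `ranked_genes` tibble.
#' @param gene_set character vector of gene ids.
#' @param weight hit-weight exponent (see [enrichment_score()]).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(ranked, gene_set, weight = 1) {
  es <- enrichment_score(ranked, gene_set, weight = weight)
  df <- tibble(rank = seq_along(es$running), running = es$running)
  ggplot(df, aes(x = .data$rank, y = .data$running)) +
    geom_line(color = "forestgreen") +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "rank in ordered gene list", y = "running enrichment score",
         subtitle = sprintf("ES = %.3f", es$es)) +
    theme_minimal()
}
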