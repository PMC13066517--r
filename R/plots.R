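#' Box plot of PC1 scores by group
#'
#' The standard display for panel validation: per-sample PC1 scores over the
#' descriptive-sequence panel, grouped by condition level, with sampling
#' time as the plotting symbol when available.
#'
#' @param pv A [validate_panel()] result.
#' @param meta Optional metadata supplying a `timepoint` column for the
#'   point symbols.
#' @return A ggplot object.
#' @importFrom ggplot2 .data
#' @export
plot_panel_scores <- function(pv, meta = NULL) {
  stopifnot(inherits(pv, "panel_validation"))
  df <- pv$scores
  if (!is.null(meta))
    df$timepoint <- meta$timepoint[match(df$sample_id, meta$sample_id)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pc1)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = pv$grouping, y = "PC1 score",
                  title = sprintf("Panel validation: %s (%d sequences)",
                                  pv$grouping, length(pv$panel))) +
    ggplot2::theme_minimal()
  if (!is.null(df$timepoint))
    p <- p + ggplot2::geom_jitter(ggplot2::aes(shape = .data$timepoint),
                                  width = 0.15, size = 1.5)
  else
    p <- p + ggplot2::geom_jitter(width = 0.15, size = 1.5)
  p
}

#' Heatmap of pull-down log2 relative abundances
#'
#' Proteins ordered by descending maximum abundance, samples grouped by
#' model label with negatives last; not-detected cells are drawn in a
#' distinct grey.
#'
#' @param pa A [relative_abundance()] result.
#' @param groups Named character vector sample -> model group.
#' @param negatives Negative-control sample IDs.
#' @return A ggplot object.
#' @export
plot_pulldown_heatmap <- function(pa, groups, negatives = character(0)) {
  stopifnot(inherits(pa, "protein_abundance"))
  L <- pa$L[pa$top_proteins, , drop = FALSE]
  all_groups <- c(groups, setNames(rep("negative", length(negatives)), negatives))
  samp_order <- colnames(L)[order(all_groups[colnames(L)] == "negative",
                                  all_groups[colnames(L)], colnames(L))]
  df <- data.frame(
    protein = factor(rep(rownames(L), ncol(L)), levels = rev(rownames(L))),
    sample = factor(rep(colnames(L), each = nrow(L)), levels = samp_order),
    L = as.vector(L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$protein,
                                   fill = .data$L)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey80",
                                 name = "log2 rel. abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
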