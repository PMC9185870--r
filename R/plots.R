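#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline geom_hline
#'   labs theme_minimal facet_wrap geom_tile scale_fill_gradient2
NULL

#' Plot ROC and precision-recall curves
#'
#' @param object A `virchip_curves` from [roc_pr_curves()].
#' @param ... Unused.
#' @return A ggplot object with ROC and PR panels.
#' @method autoplot virchip_curves
#' @export
autoplot.virchip_curves <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(x = object$roc$fpr, y = object$roc$tpr, panel = "ROC"),
    tibble(x = object$pr$recall, y = object$pr$precision, panel = "Precision-recall")
  )
  base <- tibble(panel = c("ROC", "Precision-recall"),
                 slope = c(1, 0),
                 intercept = c(0, object$prevalence))
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_line(color = "#2166AC") +
    geom_abline(data = base,
                aes(slope = .data$slope, intercept = .data$intercept),
                linetype = "dashed", color = "grey50") +
    facet_wrap(~panel, scales = "free") +
    labs(x = NULL, y = NULL,
         title = sprintf("auROC = %.3f, auPR = %.3f (baseline %.3f)",
                         object$auroc, object$aupr, object$prevalence)) +
    theme_minimal()
}

#' Plot cross-validation MCC across the hyperparameter grid
#'
#' @param object A `virchip_cv` from [mlp_grid_search()].
#' @param ... Unused.
#' @return A ggplot object: mean MCC by depth, faceted by activation,
#'   colored by L2 penalty.
#' @method autoplot virchip_cv
#' @export
autoplot.virchip_cv <- function(object, ...) {
  ggplot(object$summary,
         aes(x = factor(.data$hidden_layers), y = .data$mean_mcc,
             color = factor(.data$l2),
             shape = factor(.data$hidden_units))) +
    geom_point(size = 2) +
    facet_wrap(~activation) +
    labs(x = "hidden layers", y = "mean cross-validation MCC",
         color = "L2 penalty", shape = "hidden units") +
    theme_minimal()
}

#' Plot cluster-stability profiles
#'
#' @param object A `virchip_stability` from [cluster_stability_select()].
#' @param ... Unused.
#' @return A ggplot object of mean Jaccard stability against k for the data
#'   and the Gaussian control.
#' @method autoplot virchip_stability
#' @export
autoplot.virchip_stability <- function(object, ...) {
  df <- tidyr::pivot_longer(object$stability, c("jaccard_data", "jaccard_control"),
                            names_to = "series", values_to = "jaccard")
  df$series <- ifelse(df$series == "jaccard_data", "data", "Gaussian control")
  ggplot(df, aes(x = .data$k, y = .data$jaccard, color = .data$series)) +
    geom_line() + geom_point() +
    labs(x = "number of clusters k", y = "mean co-cluster Jaccard",
         color = NULL) +
    theme_minimal()
}

#' Heatmap of an association-matrix block
#'
#' @param object A `virchip_association`.
#' @param max_bins,max_genes Largest block to draw (default 100 x 100,
#'   taken from the bins/genes with the most non-NA entries).
#' @param ... Unused.
#' @return A ggplot tile plot; NA-masked entries are blank.
#' @method autoplot virchip_association
#' @export
autoplot.virchip_association <- function(object, max_bins = 100,
                                         max_genes = 100, ...) {
  nn_bin <- rowSums(!is.na(object$values))
  nn_gene <- colSums(!is.na(object$values))
  bins <- utils::head(order(-nn_bin), max_bins)
  genes <- utils::head(order(-nn_gene), max_genes)
  block <- object$values[bins, genes, drop = FALSE]
  df <- tidyr::expand_grid(gene = seq_along(genes), bin = seq_along(bins))
  df$r <- as.vector(block)  # column-major: bin varies fastest, matching expand_grid
  ggplot(df, aes(x = .data$gene, y = .data$bin, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#B35806", mid = "white", high = "#542788",
                         na.value = "grey92", limits = c(-1, 1)) +
    labs(x = "gene (sorted by coverage)", y = "genomic bin", fill = "Pearson r") +
    theme_minimal()
}
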