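#' Scatter of the (AG, AD) feature space
#'
#' MA-plot-style view of the gene cloud: the dense core of equally expressed
#' genes hugs `ad = 0`, and candidate DEGs sit in the sparse boundary.
#' Optionally colours known true DEGs.
#'
#' @param features a `deg_features` tibble.
#' @param truth optional character vector of true DEG identifiers.
#' @param alpha point transparency.
#' @return a ggplot object.
#' @export
plot_feature_space <- function(features, truth = NULL, alpha = 0.4) {
  features <- as_features(features)
  p <- ggplot2::ggplot(features, ggplot2::aes(x = .data$ag, y = .data$ad))
  if (is.null(truth)) {
    p <- p + ggplot2::geom_point(alpha = alpha)
  } else {
    df <- dplyr::mutate(as_tibble(features),
                        true_deg = .data$gene_id %in% truth)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ag, y = .data$ad,
                                          colour = .data$true_deg)) +
      ggplot2::geom_point(alpha = alpha) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "#D55E00"),
                                   name = "true DEG")
  }
  p + ggplot2::labs(x = "average expression (AG, log2)",
                    y = "average difference (AD, |log2 FC|)")
}

#' @rdname prune_genes
#' @param object a `deg_pruning`.
#' @export
autoplot.deg_pruning <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ag, y = .data$ad,
                               colour = .data$kept)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "#0072B2"),
                                 name = "kept") +
    ggplot2::labs(
      x = "average expression (AG, log2)",
      y = "average difference (AD, |log2 FC|)",
      title = sprintf("density pruning: r0 = %g, n0 = %d (%d / %d kept)",
                      attr(object, "r0"), attr(object, "n0"),
                      sum(object$kept), nrow(object)))
}

#' @rdname roc_curve
#' @param object a `deg_roc`.
#' @param ... unused.
#' @export
autoplot.deg_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("prefix ROC (k up to %d)", attr(object, "k_max")))
}

#' @rdname run_benchmark
#' @param object a `deg_benchmark`.
#' @export
autoplot.deg_benchmark <- function(object, ...) {
  df <- tidy(object)
  df$pruning <- ifelse(df$pruned, "pruned", "unpruned")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$partial_auc,
                                   fill = .data$pruning)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "partial AUC",
                  title = "partial AUC with and without density pruning")
}

#' Confusion-label scatter in feature space
#'
#' Colours every gene by its TP/FP/FN/TN label at a top-K cutoff, showing
#' where in the (AG, AD) plane a ranking statistic makes its mistakes.
#'
#' @param features a `deg_features` tibble.
#' @param ranking a `deg_ranking` over the same genes.
#' @param truth true DEG identifiers.
#' @param k prediction cutoff.
#' @return a ggplot object.
#' @export
plot_confusion_space <- function(features, ranking, truth, k) {
  features <- as_features(features)
  labels <- confusion_labels(ranking, truth, k)
  df <- dplyr::left_join(as_tibble(features)[, c("gene_id", "ag", "ad")],
                         labels[, c("gene_id", "label")], by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ag, y = .data$ad,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(TP = "#009E73", FP = "#D55E00",
                                            FN = "#CC79A7", TN = "grey75")) +
    ggplot2::labs(x = "average expression (AG, log2)",
                  y = "average difference (AD, |log2 FC|)",
                  title = sprintf("confusion labels at top-%d", k))
}
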