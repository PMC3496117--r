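# ggplot2 views of the main result types

#' Volcano plot of a DE gene table
#'
#' @param object a `de_genes` object.
#' @param ... unused.
#' @return A ggplot: log2 fold change against -log10 p, selected genes
#'   highlighted, with the fold-change threshold marked.
#' @method autoplot de_genes
#' @export
autoplot.de_genes <- function(object, ...) {
  fc <- log2(attr(object, "fc_min"))
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc, fc), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (resistant vs control)",
                  y = expression(-log[10] ~ p), colour = "selected") +
    ggplot2::theme_minimal()
}

#' Null distribution of the proximity permutation test
#'
#' @param object a `permutation_test` object.
#' @param ... unused.
#' @return A ggplot: histogram of null mean pairwise distances with the
#'   observed value marked.
#' @method autoplot permutation_test
#' @export
autoplot.permutation_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mean_distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "mean pairwise shortest-path distance",
                  y = "permutations",
                  title = sprintf("observed = %.3f, p = %.4g (B = %d)",
                                  object$observed, object$p_value, object$B)) +
    ggplot2::theme_minimal()
}

#' Cluster size overview of an MCL partition
#'
#' @param object an `mcl_clusters` object.
#' @param ... unused.
#' @return A ggplot: cluster sizes as bars, coloured by retention status
#'   when [filter_clusters()] has been applied.
#' @method autoplot mcl_clusters
#' @export
autoplot.mcl_clusters <- function(object, ...) {
  smry <- object$summary
  if (is.null(smry$retained)) smry$retained <- NA
  ggplot2::ggplot(smry, ggplot2::aes(x = factor(.data$cluster), y = .data$size,
                                     fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "genes", fill = "retained") +
    ggplot2::theme_minimal()
}
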