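#' MDS plot of a clustering result
#'
#' Two-dimensional classical MDS of the samples over the signature probes,
#' coloured by group, shaped by dendrogram side.
#'
#' @param object A `meth_clustering` from [evaluate_clustering()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_clustering <- function(object, ...) {
  ggplot2::ggplot(object$mds,
                  ggplot2::aes(x = .data$mds1, y = .data$mds2,
                               colour = .data$group,
                               shape = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "Group",
                  shape = "Dendrogram side",
                  title = sprintf("Sample clustering (purity %.2f)",
                                  object$purity)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of per-probe differential methylation
#'
#' Beta-scale effect size against -log10 adjusted p-value, with the 5%
#' methylation-difference floor marked.
#'
#' @param object A `diffmeth_fit` from [diff_methylation()].
#' @param delta_min Vertical reference lines at +/- this effect size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffmeth_fit <- function(object, delta_min = 0.05, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$delta_beta,
                               y = -log10(.data$p_adj))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_vline(xintercept = c(-delta_min, delta_min),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Methylation difference (case - control, beta)",
                  y = expression(-log[10] ~ "adjusted p"),
                  title = "Per-probe differential methylation") +
    ggplot2::theme_minimal()
}

#' Projection plot of held-out samples
#'
#' Held-out samples on the training MDS plane, coloured by their assigned
#' cluster side.
#'
#' @param object A `projection_result` from [project()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.projection_result <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$mds1, y = .data$mds2,
                               colour = .data$assignment)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "Assigned side",
                  title = "Held-out sample projection") +
    ggplot2::theme_minimal()
}
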