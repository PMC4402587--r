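#' Plot per-read topic distributions
#'
#' Stacked topic proportions per read, ordered by dominant topic — a quick
#' look at whether the topic space separates composition signatures.
#'
#' @param object A `tm_lda` fit.
#' @param max_reads Reads are downsampled to this many bars (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tm_lda <- function(object, max_reads = 200, ...) {
  th <- tidy(object, matrix = "theta")
  ids <- unique(th$id)
  if (length(ids) > max_reads) {
    keep <- ids[seq(1, length(ids), length.out = max_reads)]
    th <- dplyr::filter(th, .data$id %in% keep)
  }
  ord <- th |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(top = .data$topic[which.max(.data$theta)][1],
                     w = max(.data$theta)) |>
    dplyr::arrange(.data$top, dplyr::desc(.data$w))
  th$id <- factor(th$id, levels = ord$id)
  ggplot2::ggplot(th, ggplot2::aes(x = .data$id, y = .data$theta,
                                   fill = factor(.data$topic))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "read", y = expression(theta), fill = "topic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot learned SKWIC feature weights
#'
#' Heatmap of the per-cluster, per-dimension weights; rows sum to one, so a
#' bright cell marks a topic that dominates that cluster's distance.
#'
#' @param object A `skwic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skwic_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$dimension,
                                   y = factor(.data$cluster),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "dimension", y = "cluster", fill = expression(v[ik])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot a binning against its truth labels
#'
#' Cluster-by-species read counts as a tile plot; a clean diagonal-like
#' pattern means pure clusters.
#'
#' @param object A `tm_binning` with truth labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tm_binning <- function(object, ...) {
  if (is.null(object$truth)) abort("binning has no truth labels to plot against")
  ct <- binning_contingency(object$assignment, object$truth,
                            unclassified = object$excluded)
  df <- as.data.frame.table(ct$R, responseName = "reads")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$cluster,
                                   fill = .data$reads)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$reads), color = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "true species", y = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a topic-number sweep
#'
#' @param sweep A tibble from [topic_sweep()].
#' @return A ggplot object with one line per metric.
#' @export
plot_topic_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("precision", "sensitivity", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$topics, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of topics", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
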