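#' Histogram of divergence scores
#'
#' Distribution of the off-diagonal regulator -> target scores; useful for
#' eyeballing the separation the redundancy penalty has to work with.
#'
#' @param D A `"divergence_matrix"` or a `"pgrn_fit"`.
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(D, bins = 30) {
  if (inherits(D, "pgrn_fit")) D <- D$scores
  stopifnot(inherits(D, "divergence_matrix"))
  tidy(D) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::labs(x = sprintf("time-lagged %s score", attr(D, "measure")),
                  y = "regulator-target pairs") +
    ggplot2::theme_minimal()
}

#' Plot smoothed pseudo-temporal expression profiles
#'
#' @param object A `"smoothed_trajectory"`.
#' @param genes Genes to draw (default: first 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_trajectory <- function(object, genes = NULL, ...) {
  genes <- genes %||% utils::head(rownames(object$values), 8)
  tidy(object) |>
    dplyr::filter(.data$gene %in% genes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$window_center, y = .data$value,
                                 color = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime (window center)", y = "smoothed expression",
                  color = "gene") +
    ggplot2::theme_minimal()
}

#' Heatmap of a divergence matrix
#'
#' @param object A `"divergence_matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_matrix <- function(object, ...) {
  tibble::tibble(
    regulator = rep(rownames(object), times = ncol(object)),
    target = rep(colnames(object), each = nrow(object)),
    score = as.vector(unclass(object))
  ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$target, y = .data$regulator,
                                 fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target", y = "regulator",
                  fill = sprintf("%s\nscore", attr(object, "measure"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a fitted signed network as an adjacency tile map
#'
#' Retained edges are tiles colored by sign and shaded by score; empty cells
#' are unselected pairs.
#'
#' @param object A `"pgrn_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgrn_fit <- function(object, ...) {
  net <- object$network
  ggplot2::ggplot(net, ggplot2::aes(x = .data$target, y = .data$regulator,
                                    fill = .data$sign,
                                    alpha = .data$score)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(activation = "#d73027",
                                          inhibition = "#4575b4")) +
    ggplot2::scale_alpha_continuous(range = c(0.4, 1), guide = "none") +
    ggplot2::labs(x = "target", y = "regulator", fill = "sign",
                  title = sprintf("%d signed edges (measure %s, lambda %.3g)",
                                  nrow(net), object$config$measure,
                                  object$config$lam)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
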