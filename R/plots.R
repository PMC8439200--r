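#' Plot network entropy across groups
#'
#' @param entropies A data frame with columns `label` (group) and
#'   `entropy`, e.g. `purrr::map_dfr(results, glance)`.
#' @return A ggplot bar chart.
#' @export
plot_entropy <- function(entropies) {
  entropies <- as_tibble(entropies)
  entropies$label <- factor(entropies$label, levels = entropies$label)
  ggplot2::ggplot(entropies,
                  ggplot2::aes(x = .data$label, y = .data$entropy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "network structure entropy") +
    ggplot2::theme_minimal()
}

#' Plot six-pattern counts across dose groups
#'
#' @param summary Output of [summarize_yinyang()].
#' @return A ggplot faceted by pattern.
#' @export
plot_pattern_counts <- function(summary) {
  long <- tidyr::pivot_longer(summary,
                              dplyr::starts_with("n_"),
                              names_to = "pattern", values_to = "count",
                              names_prefix = "n_")
  long$group <- factor(long$group, levels = unique(summary$group))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = NULL, y = "metabolite count") +
    ggplot2::theme_minimal()
}

#' Heat map of a Kendall tau matrix
#'
#' @param x A [tau_matrix()].
#' @param ... Unused.
#' @return A ggplot tile heat map.
#' @method autoplot tau_matrix
#' @export
autoplot.tau_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x$tau, rownames = "from"), -"from",
    names_to = "to", values_to = "tau")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$from, y = .data$to,
                               fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = paste("Kendall tau,", x$condition),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Synchronous network layout plot
#'
#' Solid segments are synchronous (positive tau) edges, dashed are
#' anti-synchronous; weak edges are drawn faint.
#'
#' @param x A `sync_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sync_network
#' @export
autoplot.sync_network <- function(x, ...) {
  g <- sync_igraph(x, use_weak = TRUE)
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  pos <- tibble(node = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  e <- x$edges
  e <- dplyr::left_join(e, setNames(pos, c("from", "x1", "y1")),
                        by = "from")
  e <- dplyr::left_join(e, setNames(pos, c("to", "x2", "y2")), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2,
                   linetype = .data$tau < 0,
                   alpha = .data$edge_class != "weak",
                   linewidth = abs(.data$tau))) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "steelblue") +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linetype_manual(values = c("solid", "dashed"),
                                   guide = "none") +
    ggplot2::scale_alpha_manual(values = c(0.25, 0.9), guide = "none") +
    ggplot2::scale_linewidth(range = c(0.3, 1.2), guide = "none") +
    ggplot2::labs(title = x$condition) +
    ggplot2::theme_void()
}

#' Plot a dose trend of pattern counts
#'
#' @param counts_by_group Data frame with `group` and `count` columns (in
#'   increasing dose order).
#' @param trend Optional output of [dose_trend()] to annotate the fit.
#' @return A ggplot.
#' @export
plot_dose_trend <- function(counts_by_group, trend = NULL) {
  counts_by_group <- as_tibble(counts_by_group)
  counts_by_group$rank <- seq_len(nrow(counts_by_group))
  p <- ggplot2::ggplot(counts_by_group,
                       ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_continuous(breaks = counts_by_group$rank,
                                labels = counts_by_group$group) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(trend) && !trend$degenerate) {
    p <- p + ggplot2::geom_abline(slope = trend$slope,
                                  intercept = trend$intercept,
                                  colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("r = %.2f", trend$r))
  }
  p
}
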