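#' Plot observed vs permuted exchange-type counts
#'
#' Bars show observed family counts per exchange type; points and error
#' bars show the permutation-null mean and +/- 2 SD.
#'
#' @param object An `mge_null_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mge_null_calibration <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$exchange_type)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "steelblue",
                      alpha = 0.7) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$null_mean,
                   ymin = .data$null_mean - 2 * .data$null_sd,
                   ymax = .data$null_mean + 2 * .data$null_sd)) +
    ggplot2::labs(x = NULL, y = "families with exchange type",
                  title = "Observed vs label-permutation null") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a group-level wGRR network on a circular layout
#'
#' @param object An `mge_group_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mge_group_graph <- function(object, ...) {
  nodes <- object$nodes
  th <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  nodes$x <- cos(th)
  nodes$y <- sin(th)
  ed <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, group_a = "group_label",
                                   xa = "x", ya = "y"), by = "group_a") |>
    dplyr::left_join(dplyr::select(nodes, group_b = "group_label",
                                   xb = "x", yb = "y"), by = "group_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$mean_wgrr),
                          color = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$mge_type,
                                     size = .data$n_elements)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$group_label), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Mean wGRR between element groups")
}

#' Boxplot of per-element recombining-gene fractions by MGE type
#'
#' @param fractions Tibble from [rg_fractions()].
#' @return A ggplot object.
#' @export
plot_rg_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$mge_type, y = .data$rg_fraction,
                               fill = .data$mge_type)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "RG / (RG + NRG)") +
    ggplot2::theme_minimal()
}

#' Difference-sum ratio panel for an enrichment table
#'
#' Bars show the difference-sum ratio per category; significance stars
#' (BH-adjusted) are printed at the bar ends.
#'
#' @param enrichment Tibble from [test_enrichment()] / [fisher_bh()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$r_diff_sum, y = .data$category,
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.2,
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(over = "firebrick",
                                          under = "steelblue",
                                          ns = "grey70")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "difference-sum ratio", y = NULL) +
    ggplot2::theme_minimal()
}
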