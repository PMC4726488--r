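#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of an association scan
#'
#' Effect size against -log10 p per metabolite, faceted by contrast, with the
#' metabolome-wide Bonferroni threshold drawn as a dashed line.
#'
#' @param object An `assoc_table` from [run_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_table
#' @export
autoplot.assoc_table <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$beta, y = -log10(.data$p_value),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 na.value = "grey80") +
    ggplot2::labs(x = "effect on log concentration (case vs reference)",
                  y = expression(-log[10]~p), colour = "metabolome-wide") +
    ggplot2::theme_minimal()
}

#' Edge-rule diagnostic plot for a GGM
#'
#' Pearson against partial correlation for every metabolite pair, coloured by
#' dual-rule status; artifact-flagged pairs (near-zero Pearson, negative
#' partial) appear in their own colour.
#'
#' @param object A [build_network()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ggm
#' @export
autoplot.ggm <- function(object, ...) {
  df <- tibble::as_tibble(object$edges) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$artifact_flag ~ "artifact",
      .data$passes_dual_rule ~ "edge",
      TRUE ~ "no edge"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pearson_r, y = .data$partial_r,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(edge = "firebrick",
                                            `no edge` = "grey60",
                                            artifact = "goldenrod")) +
    ggplot2::labs(x = "Pearson correlation", y = "partial correlation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Network layout plot
#'
#' Draws the dual-rule-filtered network with a force-directed layout;
#' edge width follows the partial correlation magnitude.
#'
#' @param object A [annotate_network()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metab_network
#' @export
autoplot.metab_network <- function(object, ...) {
  g <- as_igraph_network(object)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(metabolite_id = igraph::V(g)$name,
                          x = xy[, 1], y = xy[, 2])
  el <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
  seg <- el |>
    dplyr::left_join(nodes, by = c(from = "metabolite_id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(to = "metabolite_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = abs(.data$partial_r)),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2, colour = "firebrick") +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void()
}

#' Group box plot for one metabolite
#'
#' The study's standard per-metabolite display: log concentration by group.
#'
#' @param matrix A LOG-scale [metab_matrix()].
#' @param annotation Sample annotation tibble.
#' @param metabolite Metabolite column name.
#' @return A ggplot object.
#' @export
plot_metabolite <- function(matrix, annotation, metabolite) {
  if (!metabolite %in% metabolite_ids(matrix)) {
    abort(sprintf("metabolite '%s' not in matrix.", metabolite))
  }
  df <- tibble::tibble(sample_id = matrix$sample_id,
                       value = metab_values(matrix)[, metabolite]) |>
    dplyr::inner_join(annotation[c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = sprintf("%s (log intensity)", metabolite)) +
    ggplot2::theme_minimal()
}
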