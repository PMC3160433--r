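# ggplot2 views of the result objects.

#' Heatmap of PQ same-clan frequencies
#'
#' @param object A `pq_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pq_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- df |> dplyr::rename(strain_a = "strain_b", strain_b = "strain_a")
  dplyr::bind_rows(df, df2) |>
    ggplot2::ggplot(ggplot2::aes(.data$strain_a, .data$strain_b,
                                 fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "same-clan\nfrequency",
                  title = "Polychromatic-quartet clan frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of a PQ distance matrix
#'
#' @param object A `taxon_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taxon_dist <- function(object, ...) {
  df <- tidy(object)
  df2 <- df |> dplyr::rename(taxon_a = "taxon_b", taxon_b = "taxon_a")
  dplyr::bind_rows(df, df2) |>
    ggplot2::ggplot(ggplot2::aes(.data$taxon_a, .data$taxon_b,
                                 fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - clan\nfrequency",
                  title = "PQ distances between strains") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of forest clanistic classifications
#'
#' @param report Output of [classify_forest()].
#' @return A ggplot: tree counts per classification, trivial trees shaded.
#' @export
plot_forest_classes <- function(report) {
  report |>
    dplyr::mutate(classification = factor(
      .data$classification,
      levels = c("pure", "perfect_clan", "perfect_slice", "melange"))) |>
    ggplot2::ggplot(ggplot2::aes(.data$classification, fill = .data$trivial)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "lightsteelblue")) +
    ggplot2::labs(x = NULL, y = "gene trees", fill = "trivial\n(<= 1 native)",
                  title = "Clanistic structure of the forest") +
    ggplot2::theme_minimal()
}

#' Topology triage of gene-network components
#'
#' @param metrics Output of [classify_topology()] (or
#'   [component_metrics()], which is classified on the fly).
#' @return A ggplot of density vs diameter, coloured by topology class and
#'   sized by component size.
#' @export
plot_component_topology <- function(metrics) {
  if (!"topology_class" %in% names(metrics)) {
    metrics <- classify_topology(metrics)
  }
  ggplot2::ggplot(metrics,
                  ggplot2::aes(.data$density, .data$diameter,
                               colour = .data$topology_class,
                               size = .data$n_nodes)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "component density", y = "diameter (edges)",
                  colour = "topology", size = "sequences",
                  title = "Evolutionary-mode triage of gene families") +
    ggplot2::theme_minimal()
}
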