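# ggplot2 visualizations of rank matrices and parameter heatmaps.

#' Heatmap of a rank matrix
#'
#' Entities (conditions or antibodies) on the x axis ordered best to worst
#' by overall performance, parameters on the y axis, tile fill = rank
#' (1 = best, i.e. most similar to the stable axoneme marker).
#'
#' @param object a `rank_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rank_matrix <- function(object, ...) {
  ov <- overall_performance(object)
  d <- object$ranks |>
    mutate(entity = factor(.data$entity, levels = ov$entity))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entity, y = .data$parameter,
                                  fill = .data$rank)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = format(.data$rank)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#2c7fb8", high = "#f03b20",
                                 name = "rank") +
    ggplot2::labs(x = object$axis, y = NULL,
                  title = sprintf("Per-parameter %s ranks (1 = best)",
                                  object$axis)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Antibody x condition heatmap for one parameter
#'
#' Mirrors the per-parameter heatmaps of the storage-condition analysis:
#' tile fill is the design-cell mean (averaged over donors); antibodies
#' are ordered by their mean across conditions in the parameter's better
#' direction.
#'
#' @param table parameter table from [aggregate_parameters()].
#' @param parameter which parameter to plot.
#' @param direction direction map, default [default_direction_map()].
#' @param log_values log10-transform the fill (useful for area and
#'   compactness, whose distributions are heavily right-skewed)?
#' @return a ggplot object.
#' @export
plot_parameter_heatmap <- function(table, parameter,
                                   direction = default_direction_map(),
                                   log_values = FALSE) {
  d <- filter(table, .data$parameter == !!parameter)
  if (!nrow(d)) stopf("parameter %s not present in the table", parameter)
  keys <- c("condition", "antibody")
  cell <- d |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(value = mean(.data$value), .groups = "drop")
  dir <- direction$direction[direction$parameter == parameter]
  sgn <- if (length(dir) && dir == "higher") -1 else 1
  ab_order <- cell |> group_by(.data$antibody) |>
    summarise(v = mean(.data$value), .groups = "drop") |>
    arrange(sgn * .data$v) |> pull("antibody")
  if (log_values) cell$value <- log10(cell$value)
  ggplot2::ggplot(cell,
                  ggplot2::aes(x = .data$condition,
                               y = factor(.data$antibody,
                                          levels = rev(ab_order)),
                               fill = .data$value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(name = if (log_values) "log10 value"
                                  else "value") +
    ggplot2::labs(x = "storage condition", y = NULL, title = parameter) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
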