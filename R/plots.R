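#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot a gold table as a shaded antibody x neurite heatmap
#'
#' Reproduces the familiar display of serial-immunogold scoring: one tile
#' per (antibody layer, neurite) cell, shaded by ordinal labeling
#' intensity, neurites ordered by their spatial position across the
#' cross-section.
#'
#' @param object A [gold_tbl][tabulate_gold].
#' @param bins Shade bin edges, see [shade()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gold_tbl <- function(object, bins = c(1, 2, 5, 10), ...) {
  df <- shade(as_tibble(object), bins) |>
    mutate(row = paste(.data$antibody, .data$layer, sep = ":"))
  ord <- attr(object, "neurite_order")
  if (!is.null(ord)) {
    df$neurite_id <- factor(df$neurite_id, levels = ord)
  }
  df$row <- factor(df$row, levels = rev(unique(df$row)))
  ggplot(df, aes(x = .data$neurite_id, y = .data$row,
                 fill = factor(.data$shade))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "shade") +
    ggplot2::labs(x = "neurite (by position in cross-section)",
                  y = "antibody : layer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a design-evaluation sweep
#'
#' Mean recall and precision (with +-1 SE ribbons) of confirmed identity
#' calls across the evaluated labeling designs.
#'
#' @param object A [evaluate_design()] result.
#' @param x_var Design axis to put on x (default `sections_per_run` if
#'   present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigold_design_eval <- function(object, x_var = NULL, ...) {
  df <- as_tibble(unclass(object))
  cand <- intersect(c("sections_per_run", "runs_per_antibody",
                      "run_spacing", "design"), names(df))
  x_var <- x_var %||% cand[1]
  long <- df |>
    select(all_of(c(x_var, "precision", "precision_se", "recall",
                    "recall_se"))) |>
    tidyr::pivot_longer(c("precision", "recall"), names_to = "metric") |>
    mutate(se = ifelse(.data$metric == "precision",
                       .data$precision_se, .data$recall_se))
  ggplot(long, aes(x = .data[[x_var]], y = .data$value,
                   color = .data$metric)) +
    ggplot2::geom_ribbon(aes(ymin = .data$value - .data$se,
                             ymax = .data$value + .data$se,
                             fill = .data$metric),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "mean over replicates") +
    ggplot2::theme_minimal()
}

#' Plot a circuit graph
#'
#' Nodes on a deterministic circular layout; directed edges drawn with
#' width proportional to the square root of their synapse count and
#' labeled with the count.
#'
#' @param object A [build_graph()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigold_circuit <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  pos <- tibble(node = nodes$node, px = cos(th), py = sin(th))
  ed <- object$edges |>
    left_join(rename(pos, pre = "node", x0 = "px", y0 = "py"),
              by = "pre") |>
    left_join(rename(pos, post = "node", x1 = "px", y1 = "py"),
              by = "post")
  ggplot() +
    ggplot2::geom_segment(
      data = ed,
      aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
          linewidth = .data$width),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey40") +
    ggplot2::geom_label(
      data = ed,
      aes(x = (.data$x0 + .data$x1) / 2, y = (.data$y0 + .data$y1) / 2,
          label = .data$weight), size = 3) +
    ggplot2::geom_point(data = pos, aes(.data$px, .data$py), size = 8,
                        color = "steelblue") +
    ggplot2::geom_text(data = pos, aes(.data$px, .data$py * 1.15,
                                       label = .data$node)) +
    ggplot2::scale_linewidth_identity() +
    ggplot2::theme_void()
}

#' Plot a DCV occupancy track
#'
#' Per-section dense-core-vesicle counts for selected neurites, with the
#' labeled section runs shaded, making the bursty occupancy and zero-runs
#' visible.
#'
#' @param dataset A `sigold_dataset`.
#' @param neurite_ids Neurites to show (default: first three peptidergic).
#' @return A ggplot.
#' @export
plot_dcv_tracks <- function(dataset, neurite_ids = NULL) {
  if (is.null(neurite_ids)) {
    pep <- dataset$neurites$id[lengths(dataset$neurites$true_peptides) > 0]
    neurite_ids <- utils::head(pep, 3)
  }
  trk <- filter(dataset$dcv, .data$neurite_id %in% neurite_ids)
  runs <- as_tibble(dataset$design)
  ggplot(trk, aes(x = .data$section, y = .data$dcv)) +
    ggplot2::geom_rect(data = runs,
                       aes(xmin = .data$start, xmax = .data$end,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "gold", alpha = 0.25) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~neurite_id, ncol = 1) +
    ggplot2::labs(x = "section", y = "DCV count") +
    ggplot2::theme_minimal()
}
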