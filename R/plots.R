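#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an alignment result overview
#'
#' Score versus solution size, coloured by Monte-Carlo p-value, one point
#' per alignment solution.
#'
#' @param object A `netalign_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.netalign_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_vertices, y = .data$score,
    colour = -log10(.data$p_value), shape = .data$significant
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "aligned homolog pairs", y = "solution score",
      colour = expression(-log[10] ~ p), shape = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a single alignment solution as a network
#'
#' Vertices are homolog pairs (`query|target`); edge colour encodes the
#' edge type (conserved, likely-conserved, gap, mismatch).
#'
#' @param result A `netalign_result`.
#' @param solution_id Which solution to draw (default: top-ranked).
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_solution <- function(result, solution_id = 1L, seed = 1L) {
  row <- as_tibble(result) |> filter(.data$solution_id == !!solution_id)
  if (nrow(row) == 0) abort("no such solution")
  v <- row$vertices[[1]]
  e <- row$edges[[1]]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to),
    directed = FALSE, vertices = data.frame(name = v$vertex_id)
  )
  xy <- with_rng(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    x = xy[, 1], y = xy[, 2],
    label = paste(v$query_protein, v$target_protein, sep = "|"),
    probability = v$probability
  )
  idx <- match(e$from, v$vertex_id)
  jdx <- match(e$to, v$vertex_id)
  segs <- tibble(
    x = nodes$x[idx], y = nodes$y[idx],
    xend = nodes$x[jdx], yend = nodes$y[jdx],
    edge_type = factor(e$edge_type, levels = EDGE_TYPES)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$edge_type
      ),
      linewidth = 0.8
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$probability),
      shape = 21, size = 6, colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1.4, size = 3
    ) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue", limits = c(0, 1)
    ) +
    ggplot2::scale_colour_manual(values = c(
      conserved = "forestgreen",
      likely_conserved_query = "steelblue",
      likely_conserved_target = "goldenrod",
      gap_query = "magenta3", gap_target = "darkorange",
      mismatch = "darkred"
    ), drop = FALSE) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge type", fill = "vertex\nprobability")
}
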