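#' Reactivity heatmap of a cotranscriptional matrix
#'
#' Rows are transcript lengths (ascending), columns nucleotide positions;
#' undefined cells are drawn in the null colour. Deterministic for a fixed
#' matrix and scale.
#'
#' @param object A `cotrans_matrix`.
#' @param layer Layer to draw.
#' @param limits Optional colour-scale bounds (length-2 numeric); values
#'   outside are squished.
#' @param na_colour Colour for undefined cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cotrans_matrix
#' @export
autoplot.cotrans_matrix <- function(object, layer = "reactivity",
                                    limits = NULL, na_colour = "grey80", ...) {
  if (length(object$lengths) == 0L) abort("empty matrix")
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$length_n,
                                        fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, oob = scales_squish,
                                  na.value = na_colour) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "nucleotide position", y = "transcript length (nt)",
                  fill = layer)
  p
}

# squish out-of-bounds values into the limits (avoids a scales dependency
# at the namespace level; scales is installed with ggplot2)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  scales::squish(x, range, only.finite)
}

#' Render a heatmap to an image file
#'
#' @param m A `cotrans_matrix`.
#' @param path Output file (`.png` or `.svg` by extension).
#' @param layer,limits Passed to [autoplot.cotrans_matrix()].
#' @param width,height,dpi Device geometry.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(m, path, layer = "reactivity", limits = NULL,
                           width = 7, height = 5, dpi = 150) {
  p <- autoplot(m, layer = layer, limits = limits)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Hexbin comparison of replicate reactivities
#'
#' The classic replicate-agreement view: paired surviving reactivity values
#' from [replicate_correlation()] on a 75 x 75 hexagon grid, with zero lines.
#'
#' @param report A `correlation_report`.
#' @param bins Hexagon grid size.
#' @return A ggplot object.
#' @export
plot_replicate_hexbin <- function(report, bins = 75) {
  stopifnot(inherits(report, "correlation_report"))
  ggplot2::ggplot(report$pairs,
                  ggplot2::aes(x = .data$value_a, y = .data$value_b)) +
    ggplot2::geom_hex(bins = bins) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "replicate 1 reactivity", y = "replicate 2 reactivity",
                  subtitle = sprintf("r = %.3f (n = %d)", report$r,
                                     report$n_used))
}

#' Violin plot of neighboring-transcript correlations
#'
#' @param neighbors Tibble from [neighbor_correlation()].
#' @return A ggplot object.
#' @export
plot_neighbor_violin <- function(neighbors) {
  df <- neighbors |>
    tidyr::pivot_longer(c("r_reactivity", "r_background"),
                        names_to = "layer", values_to = "r",
                        names_prefix = "r_") |>
    filter(!is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$r)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Pearson r (neighboring lengths)")
}

#' Read-retention accounting plot
#'
#' Percentage of total reads kept after adapter trimming, channel/length
#' splitting, and alignment-stage filters, from demultiplexing stats.
#'
#' @param stats Stats tibble from [demultiplex()].
#' @return A ggplot object.
#' @export
plot_read_retention <- function(stats) {
  total <- stats$count[stats$metric == "total"]
  keep <- stats |>
    filter(.data$metric %in% c("total", "assigned")) |>
    mutate(pct = 100 * .data$count / total,
           metric = factor(.data$metric, levels = c("total", "assigned")))
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$metric, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of total reads")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
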