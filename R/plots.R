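#' Plot an epitope census as a heatmap with locus facets
#'
#' @param object An `epitope_census` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitope_census <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$group, y = .data$epitope,
                                      fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::facet_grid(~locus, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "contig group", y = NULL,
                  fill = "depth-weighted\ninstances",
                  title = "CD-epitope census") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot gamma-gliadin domain maps
#'
#' One horizontal bar per protein, coloured by domain, with epitope matches
#' overlaid as points when supplied.
#'
#' @param segmentation Output of [segment_domains()].
#' @param matches Optional output of [scan_epitopes()].
#' @return A ggplot object.
#' @export
plot_domain_map <- function(segmentation, matches = NULL) {
  p <- ggplot2::ggplot(segmentation) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$id,
                   yend = .data$id, colour = .data$domain),
      linewidth = 4) +
    ggplot2::labs(x = "protein position (aa)", y = NULL, colour = "domain",
                  title = "Domain architecture") +
    ggplot2::theme_minimal()
  if (!is.null(matches) && nrow(matches) > 0) {
    p <- p + ggplot2::geom_point(
      data = matches,
      ggplot2::aes(x = .data$start + 4.5, y = .data$id),
      shape = 25, fill = "black", size = 1.5)
  }
  p
}
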