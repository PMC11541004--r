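#' Plot anti-defence frequency by oriT-relative position
#'
#' Line plot of the windowed category frequency along ORF positions
#' relative to the oriT (0 = first leading ORF), one line per category,
#' with significantly enriched positions marked.
#'
#' @param positions A `pl_position_table` / `pl_enrichment` with `f_w`
#'   (see [windowed_frequency()] and [test_position_enrichment()]).
#' @param categories Categories to draw (default: whatever is present,
#'   or the combined anti-defence class if available).
#' @param min_sequences Display threshold on `n_total` (default 0: show
#'   everything).
#' @return A ggplot object.
#' @export
plot_position_frequency <- function(positions,
                                    categories = NULL,
                                    min_sequences = 0) {
  tb <- as_tibble(positions)
  if (!"f_w" %in% names(tb)) {
    abort("positions table lacks f_w; run windowed_frequency() first")
  }
  if (is.null(categories)) {
    categories <- if ("anti_defence" %in% tb$category) {
      intersect(c("anti_defence", PL_ANTI_DEFENCE), unique(tb$category))
    } else {
      unique(tb$category)
    }
  }
  tb <- tb |>
    filter(.data$category %in% categories,
           .data$n_total >= min_sequences)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$relative_position,
                                        y = .data$f_w,
                                        colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ORF index relative to oriT (0 = first leading ORF)",
                  y = "windowed gene frequency", colour = "category") +
    ggplot2::theme_minimal()
  if ("significant" %in% names(tb) && any(tb$significant, na.rm = TRUE)) {
    p <- p + ggplot2::geom_point(
      data = filter(tb, .data$significant),
      shape = 17, size = 2)
  }
  p
}

#' @rdname plot_position_frequency
#' @param object A `pl_enrichment`.
#' @param ... Passed to [plot_position_frequency()].
#' @exportS3Method ggplot2::autoplot
autoplot.pl_enrichment <- function(object, ...) {
  plot_position_frequency(object, ...)
}

#' Gene-map plot of an anti-defence island
#'
#' Draws the leading-region genes of one contig as strand-aware arrows
#' coloured by functional category, with island spans shaded.
#'
#' @param islands A `pl_islands` tibble.
#' @param geometry The geometry table the islands were called on.
#' @param contig Contig id to draw (default: the first contig with an
#'   island).
#' @return A ggplot object.
#' @export
plot_island_map <- function(islands, geometry, contig = NULL) {
  if (nrow(islands) == 0) abort("no islands to plot")
  if (is.null(contig)) contig <- islands$contig_id[1]
  g <- geometry |>
    filter(.data$contig_id == contig, .data$relative_position >= -2)
  isl <- islands |> filter(.data$contig_id == contig)
  ggplot2::ggplot(g) +
    ggplot2::geom_rect(
      data = isl,
      ggplot2::aes(xmin = .data$start_position - 0.45,
                   xmax = .data$end_position + 0.45),
      ymin = -0.6, ymax = 0.6, fill = "grey85") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$relative_position - 0.35,
                   xend = .data$relative_position + 0.35,
                   y = 0, yend = 0, colour = .data$category),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"),
                             ends = ifelse(g$t_strand_expressible,
                                           "first", "last")),
      linewidth = 3, lineend = "butt") +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(x = "ORF index relative to oriT", y = NULL,
                  colour = "category",
                  title = sprintf("Leading region of %s", contig)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
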