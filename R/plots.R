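#' Plot a deletion size spectrum
#'
#' Size-class counts on a log scale against deletion size, with the fitted
#' reciprocal (`c / size`) reference curve.
#'
#' @param object A `deletion_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deletion_spectrum <- function(object, ...) {
  bins <- object$bins
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$size_class / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count), shape = 3,
                        colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$reciprocal_curve),
                       colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Deletion size (Mb)", y = "Frequency",
                  title = "Deletion size spectrum",
                  subtitle = "curve: frequency proportional to 1/size") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cnv_scan <- function(object, ...) autoplot(object$spectrum, ...)

#' Depth track plot for one line
#'
#' Normalized per-window depth for one line (points) over the cross-line mean
#' (line) and the mean +/- 3 standard deviation band, optionally restricted to
#' one chromosome — the standard visual check of a called deletion or
#' duplication.
#'
#' @param depth A normalized `skim_depth` table.
#' @param stats The matching `window_stats`.
#' @param line Line identifier to highlight.
#' @param chrom Optional chromosome to restrict to.
#' @param calls Optional `cnv_calls` tibble; call spans for the line are drawn
#'   as segments under the track.
#' @return A ggplot.
#' @export
plot_depth_track <- function(depth, stats, line, chrom = NULL, calls = NULL) {
  d <- depth[depth$line_id == line, , drop = FALSE]
  s <- tibble::as_tibble(stats)
  if (!is.null(chrom)) {
    d <- d[d$chrom == chrom, , drop = FALSE]
    s <- s[s$chrom == chrom, , drop = FALSE]
  }
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$start / 1e6)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mu - 3 * .data$sigma, 0),
                                      ymax = .data$mu + 3 * .data$sigma),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), colour = "goldenrod") +
    ggplot2::geom_point(data = tibble::as_tibble(d),
                        ggplot2::aes(y = .data$depth), colour = "red",
                        size = 0.4) +
    ggplot2::labs(x = "Position (Mb)", y = "Normalized depth", title = line) +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    cc <- tibble::as_tibble(calls)
    cc <- cc[cc$line_id == line, , drop = FALSE]
    if (!is.null(chrom)) cc <- cc[cc$chrom == chrom, , drop = FALSE]
    if (nrow(cc) > 0) {
      p <- p + ggplot2::geom_segment(
        data = cc,
        ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                     y = -0.15, yend = -0.15),
        colour = "darkgreen", linewidth = 1.5)
    }
  }
  if (is.null(chrom)) p <- p + ggplot2::facet_wrap(~chrom, ncol = 1)
  p
}
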