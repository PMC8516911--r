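#' Plot a median quality track with optional hits
#'
#' @param tracks a `quad_tracks` tibble.
#' @param contig contig to show.
#' @param from,to 0-based range to show (defaults to the covered range).
#' @param hits optional tibble from [scan_tracks()]; start sites are drawn
#'   as vertical marks.
#' @param regions optional tibble of intervals (e.g. MG4 calls) shaded
#'   behind the track.
#' @return a ggplot object.
#' @export
plot_track <- function(tracks, contig, from = NULL, to = NULL, hits = NULL,
                       regions = NULL) {
  d <- tracks[tracks$contig == contig, , drop = FALSE]
  if (!is.null(from)) d <- d[d$pos >= from, ]
  if (!is.null(to)) d <- d[d$pos < to, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$median_q)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strand)) +
    ggplot2::labs(x = paste0(contig, " position (0-based)"),
                  y = "median Phred quality") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    r <- regions[regions$contig == contig, ]
    p <- p + ggplot2::geom_rect(
      data = r, inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf))
  }
  if (!is.null(hits) && nrow(hits)) {
    h <- hits[hits$contig == contig, ]
    p <- p + ggplot2::geom_vline(
      data = h, linetype = "dotted", colour = "blue",
      ggplot2::aes(xintercept = .data$start_site))
  }
  p
}

#' Heatmap of a calibration grid
#'
#' Positive rate over the `M x N` grid, with cells failing the FPR bound
#' greyed out and the chosen cell outlined.
#'
#' @param object a `quad_calibration` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.quad_calibration <- function(object, ...) {
  g <- object$grid |>
    mutate(feasible = .data$fpr < object$fpr_max)
  ch <- object$chosen
  ggplot2::ggplot(g, ggplot2::aes(x = .data$M, y = .data$N)) +
    ggplot2::geom_tile(ggplot2::aes(
      fill = ifelse(.data$feasible, .data$positive_rate, NA_real_))) +
    ggplot2::geom_tile(data = ch, fill = NA, colour = "red",
                       linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strand)) +
    ggplot2::scale_fill_viridis_c(name = "positive rate",
                                  na.value = "grey85") +
    ggplot2::labs(x = "M (Phred drop)", y = "N (low-quality loci)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of MG4 structural family prevalence
#'
#' @param mg4s tibble from [call_mg4()].
#' @return a ggplot object.
#' @export
plot_family_prevalence <- function(mg4s) {
  d <- mg4s |>
    count(family = factor(.data$family, levels = FAMILY_LEVELS)) |>
    mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of MG4s") +
    ggplot2::theme_minimal()
}
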