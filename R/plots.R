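#' Plot LD decay curves
#'
#' Binned mean r-squared against distance, one line per population, with
#' the sub-sampling confidence band where present.
#'
#' @param bins Tibble from [subsample_ld()] (or [bin_ld()] with a `pop`
#'   column added).
#' @return A ggplot.
#' @export
plot_ld_decay <- function(bins) {
  d <- dplyr::filter(bins, .data$n_pairs > 0)
  d$mid_mb <- (d$dist_lo_bp + d$dist_hi_bp) / 2e6
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$mid_mb, .data$mean_r2,
                                       colour = .data$pop, fill = .data$pop))
  if (any(!is.na(d$ci_lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                               ymax = .data$ci_hi),
                                  alpha = 0.2, colour = NA, na.rm = TRUE)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Distance (Mb)", y = expression(mean ~ r^2),
                  colour = "Population", fill = "Population") +
    ggplot2::theme_minimal()
}

#' Plot windowed statistics along the genome
#'
#' @param windows A window tibble (e.g. from [pi_within()] or
#'   `tidy(wc_fst(...))`).
#' @param y Column to plot (default `value`).
#' @return A ggplot.
#' @export
plot_windows <- function(windows, y = "value") {
  ggplot2::ggplot(windows,
                  ggplot2::aes((.data$start_bp + .data$end_bp) / 2e6,
                               .data[[y]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = y) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.mantel_ibd()` shows the permutation null of the Mantel
#' statistic with the observed value; `autoplot.haplo_network()` draws the
#' haplotype network (sampled nodes sized by frequency, inferred
#' intermediates as points).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name orscpop-autoplot
NULL

#' @rdname orscpop-autoplot
#' @export
autoplot.mantel_ibd <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$r, colour = "red") +
    ggplot2::labs(x = "Permutation Mantel r", y = "Count",
                  title = sprintf("Observed r = %.3f, p = %.3g", object$r, object$p)) +
    ggplot2::theme_minimal()
}

#' @rdname orscpop-autoplot
#' @export
autoplot.haplo_network <- function(object, ...) {
  set.seed(1)  # layout only
  xy <- igraph::layout_with_fr(object$graph)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$node)]
  ed$y <- nd$y[match(ed$from, nd$node)]
  ed$xend <- nd$x[match(ed$to, nd$node)]
  ed$yend <- nd$y[match(ed$to, nd$node)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(.data$x, .data$y,
                                     size = pmax(.data$count, 0.5),
                                     colour = .data$type)) +
    ggplot2::scale_size_area(max_size = 8, guide = "none") +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_void()
}
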