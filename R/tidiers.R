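#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for fitted result objects
#'
#' `tidy()` returns the per-unit table of a result (windows, permutations,
#' contingency cells, network edges); `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name orscpop-tidiers
NULL

#' @rdname orscpop-tidiers
#' @export
tidy.wc_fst <- function(x, ...) x$windows

#' @rdname orscpop-tidiers
#' @export
glance.wc_fst <- function(x, ...) {
  tibble::tibble(genome_fst = x$genome, ci_lo = x$ci[1], ci_hi = x$ci[2],
                 overall_theta = x$overall_theta, n_windows = nrow(x$windows))
}

#' @rdname orscpop-tidiers
#' @export
tidy.mantel_ibd <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$r_perm), r = x$r_perm)
}

#' @rdname orscpop-tidiers
#' @export
glance.mantel_ibd <- function(x, ...) {
  tibble::tibble(r = x$r, r2 = x$r2, p = x$p, n = x$n, n_perm = x$n_perm)
}

#' @rdname orscpop-tidiers
#' @export
tidy.concordance <- function(x, ...) {
  as.data.frame(x$contingency) |>
    stats::setNames(c("subpop", "species_label", "n")) |>
    tibble::as_tibble()
}

#' @rdname orscpop-tidiers
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p,
                 effect_r2 = x$effect_r2, n = x$n)
}

#' @rdname orscpop-tidiers
#' @export
tidy.haplo_network <- function(x, ...) x$edges

#' @rdname orscpop-tidiers
#' @export
glance.haplo_network <- function(x, ...) {
  tibble::tibble(n_sampled = sum(x$nodes$type == "sampled"),
                 n_inferred = sum(x$nodes$type == "inferred"),
                 n_connections = length(unique(x$edges$connection)),
                 n_components = igraph::count_components(x$graph),
                 connection_limit = x$connection_limit)
}
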