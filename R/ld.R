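#' Per-population SNP filter for LD analysis
#'
#' Within the given population, keeps SNPs with at most 30 % missing data
#' and at least two accessions carrying the minor allele.
#'
#' @param g A `geno_tbl`.
#' @param pop Accession ids of the population.
#' @param max_missing Maximum missing fraction (default 0.30, inclusive).
#' @param min_carriers Minimum number of accessions carrying at least one
#'   minor allele (default 2).
#' @return The filtered `geno_tbl` restricted to `pop`.
#' @export
ld_filter <- function(g, pop, max_missing = 0.30, min_carriers = 2) {
  stopifnot(length(pop) >= 1)
  sub <- geno_subset(g, pop)
  m <- geno_calls(sub)
  miss <- rowMeans(is.na(m))
  alt <- rowSums(m, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(m))
  minor_is_alt <- alt <= tot - alt
  carriers <- ifelse(minor_is_alt,
                     rowSums(m >= 1, na.rm = TRUE),
                     rowSums(m <= 1, na.rm = TRUE))
  keep <- miss <= max_missing & carriers >= min_carriers
  out <- sub[keep, ]
  class(out) <- class(sub)
  out
}

#' Pairwise composite LD (r-squared) within a distance cap
#'
#' For every same-chromosome SNP pair at most `max_dist_bp` apart, the
#' squared Pearson correlation of dosage vectors over co-called accessions
#' (composite LD on unphased diploids). Pairs with fewer than 4 co-called
#' accessions or zero dosage variance in either vector are skipped.
#'
#' @param g A `geno_tbl` (typically after [ld_filter()]).
#' @param pop Accession ids; defaults to all accessions in `g`.
#' @param max_dist_bp Maximum pair distance (default 10 Mb).
#' @return A tibble: `chrom, snp_a, snp_b, dist_bp, r2`.
#' @export
pairwise_r2 <- function(g, pop = geno_accessions(g), max_dist_bp = 1e7) {
  sub <- geno_subset(g, pop)
  out <- lapply(split(seq_len(nrow(sub)), sub$chrom), function(idx) {
    if (length(idx) < 2) return(NULL)
    m <- t(geno_calls(sub[idx, ]))                 # accession x snp
    pos <- sub$pos[idx]
    suppressWarnings(r2 <- stats::cor(m, use = "pairwise.complete.obs")^2)
    co <- crossprod(!is.na(m))
    pairs <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
    ok <- d <= max_dist_bp & co[pairs] >= 4 & is.finite(r2[pairs])
    tibble::tibble(chrom = sub$chrom[idx[1]],
                   snp_a = colnames(m)[pairs[ok, 1]],
                   snp_b = colnames(m)[pairs[ok, 2]],
                   dist_bp = d[ok], r2 = r2[pairs][ok])
  })
  dplyr::bind_rows(out)
}

#' Bin LD pairs by distance
#'
#' Half-open bins `[lo, hi)`; a pair sitting exactly on an edge belongs to
#' the right-hand bin. Empty bins keep `n_pairs = 0` and a missing mean.
#'
#' @param pairs Tibble from [pairwise_r2()].
#' @param bin_edges_bp Increasing edge vector; default 0-10 Mb in 100-kb
#'   steps.
#' @return A tibble: `dist_lo_bp, dist_hi_bp, mean_r2, n_pairs`.
#' @export
bin_ld <- function(pairs, bin_edges_bp = seq(0, 1e7, by = 1e5)) {
  stopifnot(!is.unsorted(bin_edges_bp, strictly = TRUE), length(bin_edges_bp) >= 2)
  nb <- length(bin_edges_bp) - 1
  bin <- findInterval(pairs$dist_bp, bin_edges_bp,
                      rightmost.closed = FALSE, left.open = FALSE)
  keep <- bin >= 1 & bin <= nb
  agg <- tibble::tibble(bin = bin[keep], r2 = pairs$r2[keep]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(), .groups = "drop")
  tibble::tibble(bin = seq_len(nb),
                 dist_lo_bp = bin_edges_bp[-length(bin_edges_bp)],
                 dist_hi_bp = bin_edges_bp[-1]) |>
    dplyr::left_join(agg, by = "bin") |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) |>
    dplyr::select(-"bin")
}

#' LD decay with equal-sample-size sub-sampling confidence bands
#'
#' The reference population (one whose size equals `n_sub`, or the named
#' `reference`) is analysed once, without a confidence band. Every other
#' population is sub-sampled to `n_sub` accessions (without replacement)
#' `n_reps` times; each draw re-applies the LD SNP filter and recomputes
#' pairwise r-squared and binned means, and the band is the 2.5/97.5
#' percentile of each bin's mean across draws.
#'
#' @param g A `geno_tbl` (unfiltered; filtering happens per population and
#'   per draw).
#' @param pops Named list of accession-id vectors.
#' @param n_sub Sub-sample size (default 12).
#' @param n_reps Replicate draws (default 100).
#' @param bin_edges_bp Passed to [bin_ld()].
#' @param max_dist_bp Passed to [pairwise_r2()].
#' @param seed Integer seed.
#' @return A tibble: `pop, dist_lo_bp, dist_hi_bp, mean_r2, n_pairs,
#'   ci_lo, ci_hi` (`ci_*` missing for the reference population; for
#'   sub-sampled populations `mean_r2` is the mean over replicate bin
#'   means and `n_pairs` their average count).
#' @export
subsample_ld <- function(g, pops, n_sub = 12, n_reps = 100,
                         bin_edges_bp = seq(0, 1e7, by = 1e5),
                         max_dist_bp = 1e7, seed = 1) {
  stopifnot(!is.null(names(pops)))
  sizes <- lengths(pops)
  small <- names(pops)[sizes < n_sub]
  if (length(small) > 0) {
    stop("population(s) smaller than n_sub = ", n_sub, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  one_run <- function(ids) {
    bin_ld(pairwise_r2(ld_filter(g, ids), ids, max_dist_bp), bin_edges_bp)
  }
  with_seed(seed, {
    purrr::imap(pops, function(ids, nm) {
      if (length(ids) == n_sub) {
        one_run(ids) |>
          dplyr::mutate(pop = nm, ci_lo = NA_real_, ci_hi = NA_real_)
      } else {
        reps <- lapply(seq_len(n_reps), function(r) one_run(sample(ids, n_sub)))
        rmat <- vapply(reps, function(b) b$mean_r2, numeric(nrow(reps[[1]])))
        if (is.null(dim(rmat))) rmat <- matrix(rmat, nrow = 1)
        reps[[1]] |>
          dplyr::mutate(
            pop = nm,
            mean_r2 = rowMeans(rmat, na.rm = TRUE),
            n_pairs = as.integer(round(rowMeans(
              vapply(reps, function(b) as.numeric(b$n_pairs),
                     numeric(nrow(reps[[1]])))))),
            ci_lo = apply(rmat, 1, quantile_or_na, probs = 0.025),
            ci_hi = apply(rmat, 1, quantile_or_na, probs = 0.975))
      }
    }) |>
      dplyr::bind_rows() |>
      dplyr::relocate("pop")
  })
}

quantile_or_na <- function(v, probs) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else stats::quantile(v, probs, names = FALSE)
}
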