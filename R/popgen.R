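#' Assign SNPs to non-overlapping windows of a fixed SNP count
#'
#' Windows are consecutive blocks of exactly `snps_per_window` SNPs within
#' a chromosome; a trailing block with fewer SNPs is dropped (the dropped
#' count is messaged). Windows never span chromosomes.
#'
#' @param g A `geno_tbl` (sorted on load).
#' @param snps_per_window SNPs per window (default 100).
#' @param quiet Suppress the dropped-SNP message.
#' @return A tibble with one row per SNP kept: `snp_id, chrom, pos, window`
#'   (a chromosome-qualified window label) and `window_index` (within
#'   chromosome).
#' @export
make_windows <- function(g, snps_per_window = 100, quiet = FALSE) {
  stopifnot(snps_per_window >= 1)
  w <- geno_sites(g) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(window_index = (dplyr::row_number() - 1L) %/% snps_per_window + 1L,
                  .n_in_window = dplyr::n() %/% snps_per_window) |>
    dplyr::filter(.data$window_index <= .data$.n_in_window) |>
    dplyr::ungroup()
  dropped <- nrow(g) - nrow(w)
  if (!quiet && dropped > 0) {
    message("make_windows: ", dropped, " trailing SNP(s) not in a full window")
  }
  empty_chr <- setdiff(unique(g$chrom), unique(w$chrom))
  if (length(empty_chr) > 0) {
    warning("chromosome(s) with fewer than ", snps_per_window, " SNPs: ",
            paste(empty_chr, collapse = ", "), call. = FALSE)
  }
  w |>
    dplyr::mutate(window = paste0(.data$chrom, ":", .data$window_index)) |>
    dplyr::select("snp_id", "chrom", "pos", "window", "window_index")
}

# Weir-Cockerham (1984) per-SNP variance components for r populations.
# Returns a tibble of a, b, c per SNP (NA where theta is undefined).
wc_components <- function(g, pops) {
  stopifnot(length(pops) >= 2)
  m <- geno_calls(g)
  r <- length(pops)
  pop_names <- names(pops) %||% paste0("pop", seq_len(r))
  nmat <- pmat <- hmat <- matrix(NA_real_, nrow(m), r)
  for (j in seq_len(r)) {
    sub <- m[, pops[[j]], drop = FALSE]
    called <- !is.na(sub)
    nmat[, j] <- rowSums(called)                       # individuals called
    pmat[, j] <- rowSums(sub, na.rm = TRUE) / (2 * nmat[, j])
    hmat[, j] <- rowSums(sub == 1, na.rm = TRUE) / nmat[, j]
  }
  ok <- rowSums(nmat >= 1) == r & rowSums(nmat) >= r + 1
  nsum <- rowSums(nmat)
  nbar <- nsum / r
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pbar <- rowSums(nmat * pmat) / nsum
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / nsum
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  mono <- pbar %in% c(0, 1)                            # monomorphic across groups
  bad <- !ok | mono | !is.finite(a + b + cc)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  tibble::tibble(snp_id = rownames(m), a = a, b = b, c = cc,
                 theta = a / (a + b + cc))
}

#' Windowed Weir-Cockerham Fst
#'
#' Per-SNP theta comes from the Weir-Cockerham (1984) variance components
#' a, b, c computed from allele and heterozygote counts, with missing
#' genotypes excluded per SNP. Each window's value is the ratio of sums
#' Sum(a)/Sum(a+b+c) over its usable SNPs; the genome-wide estimate is the
#' mean of window values with an empirical 95 % confidence interval from
#' the 2.5/97.5 percentiles of the window values. SNPs monomorphic across
#' all groups (theta undefined) are excluded from window sums.
#'
#' @param g A `geno_tbl`.
#' @param pops Named list of accession-id vectors, one per population
#'   (two or more).
#' @param snps_per_window Window size in SNPs (default 100).
#' @return An object of class `wc_fst` with elements `per_snp` (tibble of
#'   components and theta), `windows` (tibble: chrom, window_index,
#'   start/end bp, n_snps, value), `genome` (mean of window values),
#'   `ci` (length-2 vector), and `overall_theta` (ratio of sums over all
#'   SNPs, reported alongside the windowed mean).
#' @export
wc_fst <- function(g, pops, snps_per_window = 100) {
  comp <- wc_components(g, pops)
  win <- make_windows(g, snps_per_window, quiet = TRUE)
  if (nrow(win) == 0) {
    return(structure(list(
      per_snp = comp,
      windows = tibble::tibble(chrom = character(0), window_index = integer(0),
                               start_bp = integer(0), end_bp = integer(0),
                               n_snps = integer(0), value = numeric(0)),
      genome = NA_real_, ci = c(NA_real_, NA_real_),
      overall_theta = sum(comp$a, na.rm = TRUE) /
        sum(comp$a + comp$b + comp$c, na.rm = TRUE),
      pops = names(pops)), class = "wc_fst"))
  }
  per_win <- win |>
    dplyr::left_join(comp, by = "snp_id") |>
    dplyr::group_by(.data$chrom, .data$window_index) |>
    dplyr::summarise(
      start_bp = min(.data$pos), end_bp = max(.data$pos),
      n_snps = dplyr::n(),
      value = sum(.data$a, na.rm = TRUE) /
        sum(.data$a + .data$b + .data$c, na.rm = TRUE),
      .groups = "drop")
  vals <- per_win$value[is.finite(per_win$value)]
  structure(list(
    per_snp = comp,
    windows = per_win,
    genome = mean(vals),
    ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
    overall_theta = sum(comp$a, na.rm = TRUE) /
      sum(comp$a + comp$b + comp$c, na.rm = TRUE),
    pops = names(pops)), class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham Fst (%s)\n", paste(x$pops, collapse = " vs ")))
  cat(sprintf("  genome mean of %d windows: %.4f  [95%% CI %.4f, %.4f]\n",
              nrow(x$windows), x$genome, x$ci[1], x$ci[2]))
  cat(sprintf("  ratio-of-sums over all SNPs: %.4f\n", x$overall_theta))
  invisible(x)
}

#' Windowed nucleotide diversity within a population
#'
#' Per SNP, the unbiased per-site heterozygosity
#' pi_i = (n/(n-1)) 2 p (1-p) over the n called alleles; a window's value
#' is the sum of its per-SNP values, and `per_kb` divides by the span (kb)
#' between the window's first and last SNP. Windows whose span is zero get
#' a missing `per_kb`.
#'
#' @param g A `geno_tbl`.
#' @param pop Accession ids of the population (at least 2).
#' @param snps_per_window Window size in SNPs.
#' @return A tibble of window statistics: `chrom, window_index, start_bp,
#'   end_bp, n_snps, value, per_kb`.
#' @export
pi_within <- function(g, pop, snps_per_window = 100) {
  stopifnot(length(pop) >= 2)
  m <- geno_calls(geno_subset(g, pop))
  n_alleles <- 2 * rowSums(!is.na(m))
  p <- rowSums(m, na.rm = TRUE) / n_alleles
  pi_snp <- ifelse(n_alleles >= 2,
                   (n_alleles / (n_alleles - 1)) * 2 * p * (1 - p), NA_real_)
  win <- make_windows(g, snps_per_window, quiet = TRUE)
  if (nrow(win) == 0) {
    return(tibble::tibble(chrom = character(0), window_index = integer(0),
                          start_bp = integer(0), end_bp = integer(0),
                          n_snps = integer(0), value = numeric(0),
                          per_kb = numeric(0)))
  }
  win |>
    dplyr::left_join(tibble::tibble(snp_id = rownames(m), pi = pi_snp),
                     by = "snp_id") |>
    dplyr::group_by(.data$chrom, .data$window_index) |>
    dplyr::summarise(
      start_bp = min(.data$pos), end_bp = max(.data$pos),
      n_snps = dplyr::n(),
      value = sum(.data$pi, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(per_kb = dplyr::if_else(
      .data$end_bp > .data$start_bp,
      .data$value / ((.data$end_bp - .data$start_bp) / 1000),
      NA_real_))
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differing sites `p` into an
#' estimated substitutions-per-site distance
#' `d = -(3/4) log(1 - (4/3) p)`. Defined for `0 <= p < 0.75`.
#'
#' @param p Proportion(s) of differing sites.
#' @return Corrected distance(s).
#' @examples
#' jc_correct(0.1)  # 0.10732
#' @export
jc_correct <- function(p) {
  if (any(!is.na(p) & (p < 0 | p >= 0.75))) {
    stop("Jukes-Cantor correction undefined for p outside [0, 0.75)", call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

# allele-sharing proportion-difference matrix between accessions:
# site distance |x - y| / 2 averaged over co-called SNPs (NA if none)
allele_sharing_p <- function(m) {
  n <- ncol(m)
  p <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[, i]
    for (j in (i + 1):n) {
      d <- abs(xi - m[, j])
      co <- sum(!is.na(d))
      p[i, j] <- p[j, i] <- if (co == 0) NA_real_ else sum(d, na.rm = TRUE) / (2 * co)
    }
  }
  p
}

#' Jukes-Cantor-corrected genetic distances
#'
#' Accession-pair distances use the allele-sharing site distance on
#' unphased dosages (0 if equal, 0.5 if one shared allele, 1 if none),
#' averaged over co-called SNPs and Jukes-Cantor corrected. With
#' `level = "group"`, each group pair's distance is the mean corrected
#' distance over its inter-group accession pairs, computed only on the
#' SNPs polymorphic within the union of the two groups (monomorphic sites
#' carry no information about a population pair); with
#' `level = "accession"` the full accession matrix is returned, computed
#' over all co-called SNPs.
#'
#' @param g A `geno_tbl`.
#' @param groups Named list of accession-id vectors.
#' @param level `"group"` or `"accession"`.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(g, groups, level = c("group", "accession")) {
  level <- match.arg(level)
  polymorphic <- function(sub) {
    alt <- rowSums(sub, na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(sub))
    tot > 0 & alt > 0 & alt < tot
  }
  m_all <- geno_calls(g)
  if (level == "accession") {
    ids <- unlist(groups, use.names = FALSE)
    sub <- m_all[, ids, drop = FALSE]
    p <- allele_sharing_p(sub)
    if (anyNA(p)) warning("accession pair(s) with no co-called SNPs", call. = FALSE)
    d <- p
    d[] <- jc_correct(as.vector(p))
    diag(d) <- 0
    return(d)
  }
  gn <- names(groups)
  stopifnot(length(groups) >= 2, !is.null(gn))
  out <- matrix(0, length(groups), length(groups), dimnames = list(gn, gn))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)[-seq_len(i)]) {
      ids <- c(groups[[i]], groups[[j]])
      sub <- m_all[, ids, drop = FALSE]
      sub <- sub[polymorphic(sub), , drop = FALSE]
      p <- allele_sharing_p(sub)
      pd <- p[groups[[i]], groups[[j]], drop = FALSE]
      if (anyNA(pd)) warning("accession pair(s) with no co-called SNPs", call. = FALSE)
      out[i, j] <- out[j, i] <- mean(jc_correct(as.vector(pd)), na.rm = TRUE)
    }
  }
  out
}

#' Neighbor-joining tree with SNP-bootstrap support
#'
#' Builds a Saitou-Nei neighbor-joining tree from a distance matrix (via
#' \pkg{ape}). `nj_bootstrap()` resamples SNPs with replacement,
#' recomputes distances and trees, and reports bipartition support.
#'
#' @param m Symmetric distance matrix with finite entries.
#' @return `nj_tree()` returns an \pkg{ape} `phylo`.
#' @export
nj_tree <- function(m) {
  if (anyNA(m)) stop("distance matrix has missing entries", call. = FALSE)
  stopifnot(nrow(m) >= 3)
  ape::nj(stats::as.dist(m))
}

#' @rdname nj_tree
#' @param g A `geno_tbl` (bootstrap resampling unit = SNP).
#' @param groups Named list of accession-id vectors passed to
#'   [pairwise_distance()].
#' @param level Distance level, as in [pairwise_distance()].
#' @param n_reps Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return `nj_bootstrap()` returns a list: `tree` (with node labels set
#'   to support counts), `support` (per internal node, out of `n_reps`).
#' @export
nj_bootstrap <- function(g, groups, level = "group", n_reps = 100, seed = 1) {
  m <- pairwise_distance(g, groups, level)
  tree <- nj_tree(m)
  boot <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      idx <- sample.int(nrow(g), replace = TRUE)
      gb <- g[idx, ]
      gb$snp_id <- sprintf("bs%06d", seq_len(nrow(gb)))   # resampled ids collide
      class(gb) <- class(g)
      nj_tree(pairwise_distance(as_geno(gb), groups, level))
    })
  })
  support <- ape::prop.clades(tree, boot, rooted = FALSE)
  support[is.na(support)] <- 0
  tree$node.label <- support
  list(tree = tree, support = support, n_reps = n_reps)
}
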