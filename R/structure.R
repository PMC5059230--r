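#' Classify accessions by ancestry threshold
#'
#' An accession whose maximum ancestry proportion reaches `threshold` is
#' assigned to that group; below the threshold (strictly less) it is
#' `admixed`. Exactly at the threshold the accession is assigned.
#'
#' @param q Ancestry tibble (`accession_id` + one column per group), as
#'   from [read_qmatrix()].
#' @param group_names Optional replacement names for the ancestry columns.
#' @param threshold Assignment threshold in (0.5, 1]; default 0.75.
#' @return A tibble: `accession_id, subpop, max_q`.
#' @export
assign_subpop <- function(q, group_names = NULL, threshold = 0.75) {
  stopifnot(threshold > 0.5, threshold <= 1)
  m <- ancestry_matrix(q)
  if (!is.null(group_names)) {
    stopifnot(length(group_names) == ncol(m))
    colnames(m) <- group_names
  }
  top <- max.col(m, ties.method = "first")
  max_q <- m[cbind(seq_len(nrow(m)), top)]
  tibble::tibble(accession_id = q$accession_id,
                 subpop = ifelse(max_q >= threshold, colnames(m)[top], "admixed"),
                 max_q = max_q)
}

#' Chi-square concordance between subpopulations and species labels
#'
#' Pearson chi-square (no continuity correction) on the subpopulation x
#' species-label contingency table, with the effect size reported as
#' Cramer's V squared, `chi2 / (n * min(rows - 1, cols - 1))`, which lies
#' in [0, 1] and equals 1 only for a perfect (block-permutation)
#' association. Admixed accessions are excluded by default.
#'
#' @param assignments Tibble with `accession_id` and `subpop` (e.g. from
#'   [assign_subpop()]).
#' @param metadata Tibble with `accession_id` and `species_label`.
#' @param exclude_admixed Drop accessions assigned `"admixed"` (default
#'   `TRUE`).
#' @param collapse_labels Optional character vector: species labels kept
#'   as-is, all others collapsed into `"other"`. `NULL` keeps all labels.
#' @return A `concordance` object: `contingency`, `chi2`, `df`, `p`,
#'   `effect_r2`, `n`.
#' @export
concordance <- function(assignments, metadata, exclude_admixed = TRUE,
                        collapse_labels = NULL) {
  x <- dplyr::inner_join(assignments, metadata[, c("accession_id", "species_label")],
                         by = "accession_id")
  if (exclude_admixed) x <- dplyr::filter(x, .data$subpop != "admixed")
  if (!is.null(collapse_labels)) {
    x$species_label <- ifelse(x$species_label %in% collapse_labels,
                              x$species_label, "other")
  }
  tab <- table(x$subpop, x$species_label)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table needs at least 2 non-empty groups and labels",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  structure(list(contingency = tab,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value,
                 effect_r2 = unname(ct$statistic) /
                   (n * min(nrow(tab) - 1, ncol(tab) - 1)),
                 n = n), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Subpopulation/species concordance: chi2 = %.3f (df = %d), p = %.3g, Cramer's V2 = %.3f, n = %d\n",
              x$chi2, x$df, x$p, x$effect_r2, x$n))
  print(x$contingency)
  invisible(x)
}

#' Species composition of each subpopulation
#'
#' Per-group percentages of each species label (rows sum to 100 within
#' rounding).
#'
#' @inheritParams concordance
#' @return A tibble: `subpop, species_label, n, pct`.
#' @export
species_composition <- function(assignments, metadata) {
  dplyr::inner_join(assignments, metadata[, c("accession_id", "species_label")],
                    by = "accession_id") |>
    dplyr::count(.data$subpop, .data$species_label, name = "n") |>
    dplyr::group_by(.data$subpop) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
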