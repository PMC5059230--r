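#' PCR indel assays for the RC and Bh4 domestication genes
#'
#' `rc_assay()` amplifies a 236-bp region spanning the functional 14-bp
#' deletion of *RC* (red pericarp); `bh4_assay()` a 227-bp region spanning
#' the 22-bp deletion of *Bh4* (black hull). The deletion product length
#' is the wild length minus the deletion.
#'
#' @return An `indel_assay` list: `locus, amplicon_wild_bp, deletion_bp`.
#' @export
rc_assay <- function() indel_assay("RC", 236, 14)

#' @rdname rc_assay
#' @export
bh4_assay <- function() indel_assay("BH4", 227, 22)

#' @rdname rc_assay
#' @param locus Locus name.
#' @param amplicon_wild_bp Wild-type product length (bp).
#' @param deletion_bp Deletion length (bp).
#' @export
indel_assay <- function(locus, amplicon_wild_bp, deletion_bp) {
  stopifnot(deletion_bp > 0, amplicon_wild_bp > deletion_bp)
  structure(list(locus = locus, amplicon_wild_bp = amplicon_wild_bp,
                 deletion_bp = deletion_bp), class = "indel_assay")
}

#' Score an indel genotype from gel band lengths
#'
#' A band within `tol_bp` of the wild-type product length scores `wild`, a
#' band at the deletion length scores `deletion`, both bands score `het`.
#' A band matching neither expectation is an error.
#'
#' @param assay An `indel_assay`.
#' @param band_lengths_bp Observed product sizes (at least one).
#' @param tol_bp Matching tolerance (default 3 bp).
#' @return `"wild"`, `"deletion"`, or `"het"`.
#' @examples
#' score_indel(rc_assay(), 236)        # wild
#' score_indel(rc_assay(), c(236, 222))  # het
#' @export
score_indel <- function(assay, band_lengths_bp, tol_bp = 3) {
  stopifnot(inherits(assay, "indel_assay"), length(band_lengths_bp) >= 1)
  del_len <- assay$amplicon_wild_bp - assay$deletion_bp
  is_wild <- abs(band_lengths_bp - assay$amplicon_wild_bp) <= tol_bp
  is_del <- abs(band_lengths_bp - del_len) <= tol_bp
  if (any(!is_wild & !is_del)) {
    stop(sprintf("band of %s bp matches neither %d (wild) nor %d (deletion) for %s",
                 paste(band_lengths_bp[!is_wild & !is_del], collapse = "/"),
                 assay$amplicon_wild_bp, del_len, assay$locus), call. = FALSE)
  }
  if (any(is_wild) && any(is_del)) "het" else if (any(is_del)) "deletion" else "wild"
}

#' Select region SNPs differentiating cultivated and wild panels
#'
#' Reproduces the extended-haplotype SNP selection around a domestication
#' locus: within the region, SNPs (single-nucleotide ref/alt only) with
#' minor allele frequency above `maf_min` and missingness below
#' `missing_max` across the combined panels are tested for an allele
#' frequency difference between the white-pericarp cultivated panel and
#' the red-pericarp wild panel (two-sided Fisher exact test on the 2x2
#' allele-count table by default; heterozygotes contribute one allele to
#' each class). SNPs with `p < p_cutoff` are returned.
#'
#' @param sativa_white `geno_tbl` of white-pericarp cultivated accessions.
#' @param orsc_red `geno_tbl` of red-pericarp wild accessions (same SNPs).
#' @param region List with `chrom`, `start`, `end` (bp, closed interval);
#'   `NULL` uses all shared SNPs.
#' @param maf_min Minimum minor allele frequency (exclusive; default 0.05).
#' @param missing_max Maximum missing fraction (exclusive; default 0.03).
#' @param p_cutoff Frequency-test cutoff (default 1e-5, exclusive).
#' @param test `"fisher"` (exact) or `"chisq"`.
#' @return A tibble of retained SNPs: `snp_id, chrom, pos, maf, missing,
#'   p_value`.
#' @export
select_region_snps <- function(sativa_white, orsc_red, region = NULL,
                               maf_min = 0.05, missing_max = 0.03,
                               p_cutoff = 1e-5, test = c("fisher", "chisq")) {
  test <- match.arg(test)
  shared <- intersect(sativa_white$snp_id, orsc_red$snp_id)
  s1 <- geno_sites(sativa_white)
  keep <- s1$snp_id %in% shared & nchar(s1$ref) == 1 & nchar(s1$alt) == 1
  if (!is.null(region)) {
    keep <- keep & s1$chrom == region$chrom &
      s1$pos >= region$start & s1$pos <= region$end
  }
  snps <- s1[keep, ]
  if (nrow(snps) == 0) {
    warning("no SNPs in the requested region", call. = FALSE)
    return(tibble::tibble(snp_id = character(0), chrom = character(0),
                          pos = integer(0), maf = numeric(0),
                          missing = numeric(0), p_value = numeric(0)))
  }
  m1 <- geno_calls(sativa_white)[snps$snp_id, , drop = FALSE]
  m2 <- geno_calls(orsc_red)[snps$snp_id, , drop = FALSE]
  comb <- cbind(m1, m2)
  missing <- rowMeans(is.na(comb))
  alt <- rowSums(comb, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(comb))
  maf <- pmin(alt, tot - alt) / tot
  pass <- maf > maf_min & missing < missing_max
  alt1 <- rowSums(m1, na.rm = TRUE); tot1 <- 2 * rowSums(!is.na(m1))
  alt2 <- rowSums(m2, na.rm = TRUE); tot2 <- 2 * rowSums(!is.na(m2))
  pv <- rep(NA_real_, nrow(snps))
  for (i in which(pass)) {
    tab <- matrix(c(alt1[i], tot1[i] - alt1[i], alt2[i], tot2[i] - alt2[i]), 2)
    pv[i] <- if (test == "fisher") {
      stats::fisher.test(tab)$p.value
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  out <- tibble::tibble(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
                        maf = maf, missing = missing, p_value = pv)
  out[pass & !is.na(pv) & pv < p_cutoff, ]
}

#' Build extended haplotypes relative to the cultivated allele
#'
#' For each selected SNP the cultivated allele is the majority allele
#' (by allele count) in the cultivated reference group; SNPs where the
#' reference is exactly tied are dropped with a warning. Each accession's
#' per-SNP state is then `cultivated` (homozygous cultivated), `wild`,
#' `heterozygous`, or `missing`.
#'
#' @param panel `geno_tbl` containing all accessions to display.
#' @param selected_snps Character vector of SNP ids (non-empty) in `panel`.
#' @param cultivated_reference Accession ids defining the cultivated
#'   allele.
#' @param focal_markers Optional character vector of marker ids (SNPs
#'   and/or indel pseudo-markers present in `panel`) whose states are the
#'   in-gene focal markers; states for these are always reported.
#' @return An `extended_haplotypes` tibble: `accession_id`, one state
#'   column per SNP (ordered by position), and a `focal` list-column of
#'   named focal-marker states.
#' @export
build_extended_haplotypes <- function(panel, selected_snps, cultivated_reference,
                                      focal_markers = character(0)) {
  stopifnot(length(selected_snps) >= 1)
  all_ids <- union(selected_snps, focal_markers)
  stopifnot(all(all_ids %in% panel$snp_id))
  m <- geno_calls(panel)[all_ids, , drop = FALSE]
  ref_m <- m[, intersect(cultivated_reference, colnames(m)), drop = FALSE]
  alt_count <- rowSums(ref_m, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(ref_m))
  cult_is_alt <- alt_count * 2 > tot
  tied <- alt_count * 2 == tot
  drop <- tied & rownames(m) %in% selected_snps & !(rownames(m) %in% focal_markers)
  if (any(drop)) {
    warning("reference tied at SNP(s) ", paste(rownames(m)[drop], collapse = ", "),
            "; dropped", call. = FALSE)
    selected_snps <- setdiff(selected_snps, rownames(m)[drop])
  }
  state_of <- function(dos, cult_alt) {
    cult_dos <- if (cult_alt) dos else 2 - dos
    out <- dplyr::case_when(is.na(cult_dos) ~ "missing",
                            cult_dos == 2 ~ "cultivated",
                            cult_dos == 1 ~ "heterozygous",
                            TRUE ~ "wild")
    out
  }
  pos <- panel$pos[match(selected_snps, panel$snp_id)]
  ordered_snps <- selected_snps[order(pos)]
  states <- vapply(ordered_snps,
                   function(s) state_of(m[s, ], cult_is_alt[s]),
                   character(ncol(m)))
  if (is.null(dim(states))) states <- matrix(states, nrow = ncol(m),
                                             dimnames = list(colnames(m), ordered_snps))
  focal <- lapply(colnames(m), function(acc) {
    vapply(focal_markers, function(s) state_of(m[s, acc], cult_is_alt[s]),
           character(1))
  })
  out <- dplyr::bind_cols(tibble::tibble(accession_id = colnames(m)),
                          tibble::as_tibble(states))
  out$focal <- focal
  class(out) <- c("extended_haplotypes", class(out))
  out
}

#' Classify introgression from focal-marker states
#'
#' An accession carrying the cultivated (or heterozygous) state at all
#' three in-gene focal markers is `introgressed`; wild at all three is
#' `wild`; any other combination — including any missing focal marker —
#' is `inconsistent`.
#'
#' @param h An `extended_haplotypes` tibble with a `focal` list-column.
#' @return `h` with a `classification` column.
#' @export
classify_introgression <- function(h) {
  stopifnot("focal" %in% names(h))
  cls <- vapply(h$focal, function(f) {
    if (length(f) == 0 || any(f == "missing")) return("inconsistent")
    if (all(f %in% c("cultivated", "heterozygous"))) return("introgressed")
    if (all(f == "wild")) return("wild")
    "inconsistent"
  }, character(1))
  h$classification <- cls
  h
}

#' Phenotype/genotype concordance at the domestication loci
#'
#' The expected pairings are white pericarp (`pericarp_score` 0) with the
#' RC deletion and red pericarp (1) with the wild allele; black hull with
#' the wild Bh4 allele and light hull with the Bh4 deletion. Heterozygous
#' indel calls are treated as carrying the knock-out. Accessions with
#' missing phenotype or genotype at a locus are not scored there.
#'
#' @param metadata Accession tibble with `pericarp_score`, `hull_color`,
#'   `rc_indel`, `bh4_indel`.
#' @return A tibble: `accession_id, locus, phenotype, genotype,
#'   concordant`, one row per scored accession x locus.
#' @export
phenotype_genotype_concordance <- function(metadata) {
  rc <- metadata |>
    dplyr::filter(!is.na(.data$pericarp_score), !is.na(.data$rc_indel),
                  .data$rc_indel != "missing") |>
    dplyr::transmute(
      .data$accession_id, locus = "RC",
      phenotype = dplyr::if_else(.data$pericarp_score < 0.5, "white", "red"),
      genotype = .data$rc_indel,
      concordant = (.data$phenotype == "white") ==
        (.data$genotype %in% c("deletion", "het")))
  bh4 <- metadata |>
    dplyr::filter(!is.na(.data$hull_color), .data$hull_color != "missing",
                  !is.na(.data$bh4_indel), .data$bh4_indel != "missing") |>
    dplyr::transmute(
      .data$accession_id, locus = "BH4",
      phenotype = .data$hull_color,
      genotype = .data$bh4_indel,
      concordant = (.data$phenotype == "light") ==
        (.data$genotype %in% c("deletion", "het")))
  dplyr::bind_rows(rc, bh4)
}
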