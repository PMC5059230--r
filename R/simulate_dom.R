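#' Simulate a domestication-introgression panel around the RC locus
#'
#' Builds a genotype panel on one chromosome arm around a focal pericarp
#' locus: a cultivated reference group (white pericarp, carrying the 14-bp
#' deletion), wild accessions (red pericarp, wild-type allele), and
#' `n_introgressed` wild accessions that carry the deletion plus an
#' extended block of cultivated alleles spanning `block_halfwidth_bp`
#' either side of the locus. The block contains `n_block_snps` strongly
#' differentiated SNPs (the two innermost are the in-gene focal SNPs);
#' background SNPs share frequencies between panels, and a few decoy SNPs
#' violate the MAF and missingness filters so SNP selection is exercised.
#' The 14-bp indel is carried as a pseudo-marker row (`alt = "DEL"`, so it
#' is never treated as a SNP) and mirrored in the metadata `rc_indel`
#' column.
#'
#' @param cfg A [sim_config()] (used for its seed).
#' @param truth Truth list to extend (may be `NULL`).
#' @param n_cultivated,n_wild,n_introgressed Accession counts.
#' @param center_bp Focal locus position (chromosome 7).
#' @param block_halfwidth_bp Half-width of the introgressed/differentiated
#'   block; `0` leaves only the focal indel different between classes.
#' @param n_block_snps SNPs in the differentiated block.
#' @param region_halfwidth_bp Half-width of the analysis region.
#' @param n_background,n_lowmaf,n_highmiss,n_outside Background and decoy
#'   SNP counts (shared frequencies; MAF < 0.05; > 3 % missing; outside the
#'   region).
#' @param n_discordant Wild accessions planted with a white pericarp
#'   phenotype but a wild-type RC allele (phenotype/genotype discordance).
#' @return A list with `genotypes`, `metadata`, and `truth` (adds
#'   `introgressed_ids`, `block_snp_ids`, `focal_snp_ids`, `indel_id`,
#'   `region`).
#' @export
simulate_domestication_panel <- function(cfg, truth = NULL,
                                         n_cultivated = 40, n_wild = 70,
                                         n_introgressed = 10,
                                         center_bp = 6070000L,
                                         block_halfwidth_bp = 290000L,
                                         n_block_snps = 40,
                                         region_halfwidth_bp = 290000L,
                                         n_background = 60, n_lowmaf = 5,
                                         n_highmiss = 5, n_outside = 10,
                                         n_discordant = 0) {
  stopifnot(inherits(cfg, "sim_config"), n_introgressed <= n_wild + n_introgressed)
  with_seed(cfg$seed + 202L, {
    chrom <- "7"
    has_block <- block_halfwidth_bp > 0 && n_block_snps > 0
    focal_pos <- c(center_bp - 500L, center_bp + 500L)
    pos_block <- if (has_block) {
      p <- sample(setdiff(seq(center_bp - block_halfwidth_bp,
                              center_bp + block_halfwidth_bp), focal_pos),
                  max(n_block_snps - 2, 0))
      sort(c(p, focal_pos))  # in-gene focal SNPs
    } else integer(0)
    rand_pos <- function(n, lo, hi) if (n > 0) sort(sample(seq(lo, hi), n)) else integer(0)
    pos_bg <- rand_pos(n_background, center_bp - region_halfwidth_bp,
                       center_bp + region_halfwidth_bp)
    pos_lm <- rand_pos(n_lowmaf, center_bp - region_halfwidth_bp,
                       center_bp + region_halfwidth_bp)
    pos_hm <- rand_pos(n_highmiss, center_bp - region_halfwidth_bp,
                       center_bp + region_halfwidth_bp)
    pos_out <- rand_pos(n_outside, center_bp + region_halfwidth_bp + 100000L,
                        center_bp + region_halfwidth_bp + 1000000L)

    cls <- c(rep("block", length(pos_block)), rep("bg", n_background),
             rep("lowmaf", n_lowmaf), rep("highmiss", n_highmiss),
             rep("bg", n_outside))
    pos <- c(pos_block, pos_bg, pos_lm, pos_hm, pos_out)
    while (anyDuplicated(pos) || any(pos[-seq_along(pos_block)] %in% focal_pos)) {
      bump <- duplicated(pos) | (seq_along(pos) > length(pos_block) & pos %in% focal_pos)
      pos[bump] <- pos[bump] + 1L
    }
    S <- length(pos)
    p_shared <- stats::runif(S, 0.1, 0.9)
    p_cult <- ifelse(cls == "block", 0.97, ifelse(cls == "lowmaf", 0.02, p_shared))
    p_wild <- ifelse(cls == "block", 0.03, ifelse(cls == "lowmaf", 0.02, p_shared))
    focal_idx <- if (has_block) which(pos %in% c(center_bp - 500L, center_bp + 500L)) else integer(0)
    p_cult[focal_idx] <- 1; p_wild[focal_idx] <- 0

    ids <- c(sprintf("CUL_%03d", seq_len(n_cultivated)),
             sprintf("WLD_%03d", seq_len(n_wild)),
             sprintf("INT_%03d", seq_len(n_introgressed)))
    class_of <- rep(c("cultivated", "wild", "introgressed"),
                    c(n_cultivated, n_wild, n_introgressed))
    n <- length(ids)
    calls <- matrix(NA_integer_, S, n, dimnames = list(NULL, ids))
    for (i in seq_len(n)) {
      p <- if (class_of[i] == "cultivated") p_cult else p_wild
      calls[, i] <- stats::rbinom(S, 2, p)
    }
    if (n_introgressed > 0 && has_block) {
      calls[cls == "block", class_of == "introgressed"] <- 2L  # homozygous cultivated block
    }
    hm <- which(cls == "highmiss")
    for (s in hm) {
      drop <- sample(n, max(1, ceiling(0.08 * n)))
      calls[s, drop] <- NA_integer_
    }

    ord <- order(pos)
    sites <- tibble::tibble(
      snp_id = sprintf("RC_S%04d", seq_len(S)), chrom = chrom, pos = pos,
      ref = "A", alt = "G")[ord, ]
    sites$snp_id <- sprintf("RC_S%04d", seq_len(S))   # ids follow sorted order
    calls <- calls[ord, , drop = FALSE]
    cls <- cls[ord]
    focal_snp_ids <- sites$snp_id[sites$pos %in% c(center_bp - 500L, center_bp + 500L)]

    # the 14-bp functional indel as a pseudo-marker row (alt = "DEL")
    indel_dos <- ifelse(class_of == "wild", 0L, 2L)
    indel <- tibble::tibble(snp_id = "RC_ind14", chrom = chrom,
                            pos = center_bp, ref = "N", alt = "DEL")
    g <- geno_from_matrix(
      dplyr::bind_rows(sites, indel),
      rbind(calls, matrix(indel_dos, 1, n, dimnames = list(NULL, ids))))

    rc <- c(cultivated = "deletion", wild = "wild", introgressed = "deletion")[class_of]
    pericarp <- c(cultivated = 0, wild = 1, introgressed = 0)[class_of]
    bh4 <- c(cultivated = "deletion", wild = "wild", introgressed = "wild")[class_of]
    hull <- c(cultivated = "light", wild = "black", introgressed = "black")[class_of]
    if (n_discordant > 0) {
      disc <- which(class_of == "wild")[seq_len(min(n_discordant, n_wild))]
      pericarp[disc] <- 0   # white pericarp without the deletion
    } else {
      disc <- integer(0)
    }
    metadata <- tibble::tibble(
      accession_id = ids,
      species_label = ifelse(class_of == "cultivated", "O. sativa-subpop", "O. rufipogon"),
      country = NA_character_, latitude = NA_real_, longitude = NA_real_,
      subpop = ifelse(class_of == "cultivated", "sativa", "W1"),
      cp_group = NA_character_, hull_color = hull, pericarp_score = pericarp,
      rc_indel = rc, bh4_indel = bh4)

    truth <- utils::modifyList(truth %||% list(), list(
      introgressed_ids = ids[class_of == "introgressed"],
      block_snp_ids = sites$snp_id[cls == "block"],
      focal_snp_ids = focal_snp_ids,
      indel_id = "RC_ind14",
      discordant_ids = ids[disc],
      region = list(chrom = chrom, start = center_bp - region_halfwidth_bp,
                    end = center_bp + region_halfwidth_bp)))
    list(genotypes = g, metadata = metadata, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
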