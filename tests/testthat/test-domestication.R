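test_that("indel assays score wild, deletion, and het bands with tolerance", {
  expect_equal(score_indel(rc_assay(), 236), "wild")
  expect_equal(score_indel(rc_assay(), 222), "deletion")   # 236 - 14
  expect_equal(score_indel(rc_assay(), c(236, 222)), "het")
  expect_equal(score_indel(bh4_assay(), 227), "wild")
  expect_equal(score_indel(bh4_assay(), c(227, 205)), "het")  # 227 - 22
  expect_equal(score_indel(rc_assay(), 234), "wild")       # within +-3 bp
  expect_error(score_indel(rc_assay(), 250), "matches neither")
  expect_equal(rc_assay()$amplicon_wild_bp - rc_assay()$deletion_bp, 222)
  expect_equal(bh4_assay()$amplicon_wild_bp - bh4_assay()$deletion_bp, 205)
})

test_that("SNP selection applies MAF, missingness, and frequency-test rules in order", {
  # panel: 20 cultivated + 20 wild accessions, 4 SNPs:
  # s1 fully differentiated (selected), s2 MAF 0.04 (excluded),
  # s3 5% missing (excluded), s4 shared frequency (fails the test)
  n <- 20
  cult <- matrix(0L, 4, n); wild <- matrix(0L, 4, n)
  cult[1, ] <- 2L; wild[1, ] <- 0L
  cult[2, ] <- 0L; cult[2, 1:3] <- 1L; wild[2, ] <- 0L      # MAF 3/80
  cult[3, ] <- 2L; wild[3, ] <- 0L; wild[3, 1:2] <- NA      # 5% missing
  cult[4, ] <- 1L; wild[4, ] <- 1L
  colnames(cult) <- paste0("c", 1:n); colnames(wild) <- paste0("w", 1:n)
  gs <- toy_geno(cult); gw <- toy_geno(wild)
  sel <- select_region_snps(gs, gw)
  expect_equal(sel$snp_id, "s1")
  expect_lt(sel$p_value, 1e-5)

  # indel pseudo-markers (multi-character alleles) are never treated as SNPs
  gs2 <- gs; gs2$alt[1] <- "DEL"
  gw2 <- gw; gw2$alt[1] <- "DEL"
  expect_warning(sel2 <- select_region_snps(gs2, gw2,
                                            region = list(chrom = "1", start = 1,
                                                          end = 900)),
                 "no SNPs")
  expect_equal(nrow(sel2), 0)
})

test_that("Fisher p-values match hypergeometric enumeration and survive relabeling", {
  set.seed(13)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    got <- stats::fisher.test(tab)$p.value
    expect_equal(got, fisher_oracle(tab), tolerance = 1e-9)
  }

  # selection is invariant to accession order and allele relabeling
  n <- 16
  cult <- matrix(rbinom(5 * n, 2, 0.9), 5, n)
  wild <- matrix(rbinom(5 * n, 2, 0.05), 5, n)
  colnames(cult) <- paste0("c", 1:n); colnames(wild) <- paste0("w", 1:n)
  s_fwd <- select_region_snps(toy_geno(cult), toy_geno(wild))
  s_shuf <- select_region_snps(toy_geno(cult[, sample(n)]),
                               toy_geno(wild[, sample(n)]))
  expect_equal(s_fwd$snp_id, s_shuf$snp_id)
  s_flip <- select_region_snps(toy_geno(2L - cult), toy_geno(2L - wild))
  expect_equal(s_fwd$snp_id, s_flip$snp_id)
  expect_equal(s_fwd$p_value, s_flip$p_value, tolerance = 1e-12)
})

test_that("extended haplotypes colour accessions relative to the cultivated allele", {
  n <- 10
  cult <- matrix(2L, 3, n); colnames(cult) <- paste0("c", 1:n)
  test_acc <- cbind(all_cult = c(2L, 2L, 2L), het = c(2L, 1L, 2L),
                    wildy = c(0L, 0L, 0L), missing1 = c(2L, NA, 2L))
  panel <- toy_geno(cbind(cult, test_acc))
  eh <- build_extended_haplotypes(panel, c("s1", "s2", "s3"), paste0("c", 1:n))
  expect_equal(unname(unlist(eh[eh$accession_id == "all_cult", c("s1", "s2", "s3")])),
               rep("cultivated", 3))
  expect_equal(eh$s2[eh$accession_id == "het"], "heterozygous")
  expect_equal(unname(unlist(eh[eh$accession_id == "wildy", c("s1", "s2", "s3")])),
               rep("wild", 3))
  expect_equal(eh$s2[eh$accession_id == "missing1"], "missing")

  # a tied reference drops the SNP with a warning
  cult_tied <- cult; cult_tied[2, ] <- rep(c(0L, 2L), n / 2)
  panel2 <- toy_geno(cbind(cult_tied, test_acc))
  expect_warning(eh2 <- build_extended_haplotypes(panel2, c("s1", "s2", "s3"),
                                                  paste0("c", 1:n)),
                 "tied")
  expect_false("s2" %in% names(eh2))
})

test_that("introgression calls follow the three-focal-marker rule", {
  mk <- function(f) tibble::tibble(accession_id = "x",
                                   focal = list(c(a = f[1], b = f[2], c = f[3])))
  expect_equal(classify_introgression(mk(c("cultivated", "cultivated", "cultivated")))$classification,
               "introgressed")
  expect_equal(classify_introgression(mk(c("cultivated", "heterozygous", "cultivated")))$classification,
               "introgressed")
  expect_equal(classify_introgression(mk(c("wild", "wild", "wild")))$classification,
               "wild")
  expect_equal(classify_introgression(mk(c("cultivated", "wild", "wild")))$classification,
               "inconsistent")
  expect_equal(classify_introgression(mk(c("cultivated", "missing", "cultivated")))$classification,
               "inconsistent")
})

test_that("planted introgression and the 40-SNP block are recovered exactly", {
  cfg <- sim_config(n_snps = 50, seed = 41)
  dom <- simulate_domestication_panel(cfg, NULL, n_cultivated = 40, n_wild = 70,
                                      n_introgressed = 10)
  md <- dom$metadata
  cult <- md$accession_id[md$subpop == "sativa"]
  wild_red <- md$accession_id[md$subpop != "sativa" & md$pericarp_score == 1]
  sel <- select_region_snps(geno_subset(dom$genotypes, cult),
                            geno_subset(dom$genotypes, wild_red),
                            region = dom$truth$region)
  expect_setequal(sel$snp_id, dom$truth$block_snp_ids)
  expect_equal(nrow(sel), 40)

  eh <- build_extended_haplotypes(
    dom$genotypes, sel$snp_id, cult,
    focal_markers = c(dom$truth$focal_snp_ids, dom$truth$indel_id))
  cls <- classify_introgression(eh)
  wild_ids <- md$accession_id[md$subpop != "sativa"]
  flagged <- cls$accession_id[cls$classification == "introgressed" &
                                cls$accession_id %in% wild_ids]
  expect_setequal(flagged, dom$truth$introgressed_ids)

  # introgressed accessions carry a contiguous cultivated block
  states <- unlist(cls[cls$accession_id == dom$truth$introgressed_ids[1],
                       sel$snp_id[order(sel$pos)]])
  expect_true(all(states == "cultivated"))
})

test_that("phenotype/genotype concordance reports exactly the planted discordants", {
  cfg <- sim_config(n_snps = 50, seed = 43)
  dom <- simulate_domestication_panel(cfg, NULL, n_discordant = 2)
  rep_tab <- phenotype_genotype_concordance(dom$metadata)
  rc <- rep_tab[rep_tab$locus == "RC", ]
  expect_setequal(rc$accession_id[!rc$concordant], dom$truth$discordant_ids)
  expect_equal(sum(!rc$concordant), 2)
  bh <- rep_tab[rep_tab$locus == "BH4", ]
  expect_true(all(bh$concordant))

  # the white-hull / wild-Bh4 case is reported discordant
  one <- tibble::tibble(accession_id = "NSF474", species_label = "O. rufipogon",
                        hull_color = "light", pericarp_score = 1,
                        rc_indel = "wild", bh4_indel = "wild")
  out <- phenotype_genotype_concordance(one)
  expect_false(out$concordant[out$locus == "BH4"])
  expect_true(out$concordant[out$locus == "RC"])
})
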