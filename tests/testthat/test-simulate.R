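test_that("the generator is a pure function of config and seed", {
  cfg <- sim_config(n_snps = 300, seed = 5, n_per_group = c(8, 8), K = 2,
                    n_admixed = 4, species_probs = c(0.9, 0.1))
  s1 <- simulate_structured_genotypes(cfg)
  s2 <- simulate_structured_genotypes(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_structured_genotypes(sim_config(n_snps = 300, seed = 6,
                                                 n_per_group = c(8, 8), K = 2,
                                                 n_admixed = 4))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("undifferentiated groups give near-zero genome-wide theta", {
  cfg <- sim_config(K = 2, fst_targets = 0, n_per_group = c(50, 50),
                    n_admixed = 0, n_snps = 2000, missing_rate = 0,
                    seed = 21, species_probs = c(1, 0))
  s <- simulate_structured_genotypes(cfg)
  pops <- split(s$metadata$accession_id, s$metadata$subpop)
  f <- wc_fst(s$genotypes, pops)
  expect_lt(abs(f$genome), 0.01)
})

test_that("windowed Fst recovers the planted differentiation F = 0.2", {
  cfg <- sim_config(K = 2, fst_targets = 0.2, n_per_group = c(50, 50),
                    n_admixed = 0, n_snps = 5000, missing_rate = 0,
                    seed = 1, species_probs = c(1, 0))
  s <- simulate_structured_genotypes(cfg)
  pops <- split(s$metadata$accession_id, s$metadata$subpop)
  f <- wc_fst(s$genotypes, pops)
  expect_lt(abs(mean(f$windows$value) - 0.2), 0.03)
})

test_that("simulated panels survive a write/read round trip unchanged", {
  cfg <- sim_config(n_snps = 150, seed = 9, K = 2, n_per_group = c(6, 6),
                    n_admixed = 3, missing_rate = 0.2)
  s <- simulate_structured_genotypes(cfg)
  md <- simulate_geography(s$metadata, s$truth, seed = 2)

  gp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(s$genotypes, gp, format = "table")
  expect_equal(read_genotypes(gp), s$genotypes)

  mp <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(md, mp)
  md2 <- read_metadata(mp)
  expect_equal(md2$latitude, md$latitude, tolerance = 1e-9)
  expect_equal(md2$subpop, md$subpop)

  qp <- withr::local_tempfile()
  write_qmatrix(s$truth$true_q, qp)
  q2 <- read_qmatrix(qp, s$truth$true_q$accession_id)
  expect_equal(as.matrix(q2[, -1]), as.matrix(s$truth$true_q[, -1]),
               ignore_attr = TRUE, tolerance = 1e-7)

  cp <- simulate_chloroplast(cfg, s$truth)
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_cp_alignment(cp, ap)
  cp2 <- read_cp_alignment(ap)
  expect_equal(cp2$alleles, cp$alleles)
  expect_equal(cp2$sites, cp$sites)

  fp <- withr::local_tempfile(fileext = ".fasta")
  write_cp_fasta(cp, fp)
  cp3 <- read_cp_fasta(fp)
  expect_equal(tibble::as_tibble(cp3$alleles[, -2]), tibble::as_tibble(cp$alleles[, -2]))
})

test_that("geography respects jitter and spread settings and tracks ancestry", {
  cfg <- sim_config(K = 3, n_per_group = c(5, 5, 5), n_admixed = 3,
                    n_snps = 50, seed = 4)
  s <- simulate_structured_genotypes(cfg)
  md0 <- simulate_geography(s$metadata, s$truth, jitter_km = 0, seed = 1)
  per_group <- split(md0$latitude[md0$subpop != "admixed"],
                     md0$subpop[md0$subpop != "admixed"])
  for (v in per_group) expect_equal(max(v) - min(v), 0)

  md1 <- simulate_geography(s$metadata, s$truth, centroid_spread_km = 0,
                            jitter_km = 0, seed = 1)
  expect_equal(max(md1$latitude) - min(md1$latitude), 0)
  # degenerate geography: Mantel refuses the zero-variance matrix
  gd <- suppressMessages(geo_dist_matrix(md1))
  expect_error(mantel_test(gd + diag(nrow(gd)) * 0, gd, n_perm = 10),
               "degenerate")
})

test_that("strongly spread groups produce a detectable isolation-by-distance signal", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(K = 3, n_per_group = c(10, 10, 10), n_admixed = 0,
                      n_snps = 400, seed = seed, missing_rate = 0,
                      species_probs = c(1, 0, 1))
    s <- simulate_structured_genotypes(cfg)
    md <- simulate_geography(s$metadata, s$truth, centroid_spread_km = 2000,
                             jitter_km = 50, seed = seed + 100)
    gen <- pairwise_distance(s$genotypes, list(all = md$accession_id),
                             level = "accession")
    geo <- geo_dist_matrix(md)
    mt <- mantel_test(gen, geo, n_perm = 199, seed = seed)
    if (mt$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)   # >= 90% of seeded runs
})

test_that("chloroplast walks produce the planted haplotype structure", {
  base <- sim_config(K = 3, n_per_group = c(6, 6, 6), n_admixed = 0,
                     n_snps = 50, seed = 13)
  s <- simulate_structured_genotypes(base)

  # theta 0 and no extra steps: everyone shares the root; one-node network
  cfg0 <- sim_config(K = 3, n_per_group = c(6, 6, 6), n_admixed = 0,
                     n_snps = 50, seed = 13, theta_cp = 0)
  aln0 <- simulate_chloroplast(cfg0, s$truth, extra_step_probs = c(1, 0, 0),
                               n_outgroups = 0)
  haps0 <- collapse_haplotypes(aln0)
  expect_equal(nrow(haps0), 1)
  expect_equal(haps0$count, 18)
  net0 <- build_network(haps0)
  expect_equal(nrow(net0$edges), 0)

  # default steps: at least K distinct haplotypes, frequency conserved
  aln <- simulate_chloroplast(base, s$truth)
  haps <- collapse_haplotypes(aln)
  expect_gte(nrow(haps), 3)
  expect_equal(sum(haps$count), nrow(aln$alleles))

  # requesting more walk steps than sites fails
  expect_error(simulate_chloroplast(
    sim_config(K = 6, n_snps = 50, theta_cp = 10, n_cp_sites = 25), s$truth),
    "exceed")
})

test_that("founder mutation walks are recoverable from the network", {
  cfg <- sim_config(K = 3, n_per_group = c(12, 12, 12), n_admixed = 0,
                    n_snps = 50, seed = 31, theta_cp = 3)
  s <- simulate_structured_genotypes(cfg)
  aln <- simulate_chloroplast(cfg, s$truth, p_intermediate = 0.6,
                              extra_step_probs = c(1, 0, 0), n_outgroups = 0)
  tr <- attr(aln, "cp_truth")
  haps <- collapse_haplotypes(aln)
  net <- build_network(haps, connection_limit = 6)
  nd <- network_distances(net)

  seq_of <- function(id) haps$haplotype[vapply(haps$accessions,
                                               function(a) id %in% a, logical(1))]
  for (k in seq_len(3)) {
    ids <- s$metadata$accession_id[s$metadata$subpop == s$truth$groups[k]]
    pos_tab <- tr$walk_pos[ids]
    pos_sorted <- sort(unique(pos_tab))
    if (length(pos_sorted) < 2) next
    for (i in seq_len(length(pos_sorted) - 1)) {
      h1 <- seq_of(names(pos_tab)[pos_tab == pos_sorted[i]][1])
      h2 <- seq_of(names(pos_tab)[pos_tab == pos_sorted[i + 1]][1])
      # consecutive sampled walk states sit at their step difference
      expect_equal(unname(nd[h1, h2]),
                   pos_sorted[i + 1] - pos_sorted[i])
    }
  }
})

test_that("domestication panel plants a recoverable introgression signal", {
  cfg <- sim_config(n_snps = 50, seed = 17)

  # no introgressed accessions: classifier flags nobody among the wild
  dom0 <- simulate_domestication_panel(cfg, NULL, n_introgressed = 0)
  cult <- dom0$metadata$accession_id[dom0$metadata$subpop == "sativa"]
  sel0 <- select_region_snps(
    geno_subset(dom0$genotypes, cult),
    geno_subset(dom0$genotypes,
                dom0$metadata$accession_id[dom0$metadata$pericarp_score == 1]),
    dom0$truth$region)
  eh0 <- classify_introgression(build_extended_haplotypes(
    dom0$genotypes, sel0$snp_id, cult,
    focal_markers = c(dom0$truth$focal_snp_ids, dom0$truth$indel_id)))
  wild0 <- dom0$metadata$accession_id[dom0$metadata$subpop != "sativa"]
  expect_equal(sum(eh0$classification == "introgressed" &
                     eh0$accession_id %in% wild0), 0)

  # zero block width: only the focal indel differs, so no SNPs are selected
  domz <- simulate_domestication_panel(cfg, NULL, block_halfwidth_bp = 0,
                                       n_background = 0, n_lowmaf = 0,
                                       n_highmiss = 0, n_outside = 0)
  cz <- domz$metadata$accession_id[domz$metadata$subpop == "sativa"]
  expect_warning(
    selz <- select_region_snps(
      geno_subset(domz$genotypes, cz),
      geno_subset(domz$genotypes,
                  domz$metadata$accession_id[domz$metadata$pericarp_score == 1]),
      domz$truth$region),
    "no SNPs")
  expect_equal(nrow(selz), 0)
})
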