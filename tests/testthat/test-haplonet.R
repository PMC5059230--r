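toy_aln <- function(seqs, groups = NULL, kinds = NULL) {
  m <- do.call(rbind, strsplit(seqs, ""))
  colnames(m) <- sprintf("cp%02d", seq_len(ncol(m)))
  ids <- names(seqs) %||% paste0("acc", seq_along(seqs))
  if (is.null(groups)) groups <- rep("W1", length(seqs))
  cp_aln(
    dplyr::bind_cols(tibble::tibble(accession_id = ids, group = groups),
                     tibble::as_tibble(m)),
    tibble::tibble(site_id = colnames(m),
                   kind = kinds %||% rep("SNP", ncol(m)),
                   ancestral = NA_character_, derived = NA_character_))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("haplotype collapse counts, orders, and conserves frequencies", {
  a <- toy_aln(c("AA", "AA", "AT"), groups = c("W1", "W2", "W1"))
  h <- collapse_haplotypes(a)
  expect_equal(h$count, c(2, 1))
  expect_equal(h$haplotype, c("H1", "H2"))
  expect_equal(h$n_W1, c(1L, 1L))
  expect_equal(h$n_W2, c(1L, 0L))
  expect_equal(sum(h$count), 3)

  a3 <- toy_aln(c("CC", "CC", "CC"))
  h3 <- collapse_haplotypes(a3)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$count, 3)

  # ties broken lexicographically for deterministic numbering
  atie <- toy_aln(c("GG", "AA"))
  expect_equal(collapse_haplotypes(atie)$sequence, c("AA", "GG"))

  # missing rows excluded, not imputed
  am <- toy_aln(c("AA", "AT"))
  am$alleles$cp01[2] <- NA
  expect_message(hm <- collapse_haplotypes(am), "1 accession")
  expect_equal(sum(hm$count), 1)

  empty <- toy_aln(c("AA"))
  empty$alleles <- empty$alleles[0, ]
  expect_error(collapse_haplotypes(empty), "empty")
})

test_that("network construction follows the minimum-spanning rule with private intermediates", {
  # two haplotypes one step apart: a single edge, no inferred nodes
  h <- collapse_haplotypes(toy_aln(c("AAA", "AAT")))
  net <- build_network(h)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sum(net$nodes$type == "inferred"), 0)

  # distances 1,1,2: path through the middle; the distance-2 pair adds nothing
  h2 <- collapse_haplotypes(toy_aln(c("AA", "AT", "TT"), groups = rep("W1", 3)))
  net2 <- build_network(h2)
  expect_equal(nrow(net2$edges), 2)
  expect_equal(length(unique(net2$edges$connection)), 2)
  nd <- network_distances(net2)
  expect_equal(max(nd), 2)

  # a connection of length 3 introduces 2 inferred intermediates
  h3 <- collapse_haplotypes(toy_aln(c("AAA", "TTT")))
  net3 <- build_network(h3)
  expect_equal(sum(net3$nodes$type == "inferred"), 2)
  expect_equal(nrow(net3$edges), 3)
  expect_equal(unname(network_distances(net3)["H1", "H2"]), 3)

  # beyond the connection limit the pair stays disconnected
  net3b <- build_network(h3, connection_limit = 2)
  expect_equal(nrow(net3b$edges), 0)
  expect_true(is.infinite(network_distances(net3b)["H1", "H2"]))
})

test_that("equally parsimonious alternatives are all retained and create loops", {
  # square: 0000, 1100, 0011, 1111 — H(0000,1100) = 2 etc.; the two
  # two-step routes between opposite corners tie and must both survive
  seqs <- c("AAAA", "TTAA", "AATT", "TTTT")
  h <- collapse_haplotypes(toy_aln(seqs))
  net <- build_network(h)
  # all four distance-2 connections added (no pair joined at <= 2 beforehand)
  expect_equal(length(unique(net$edges$connection)), 4)
  g <- net$graph
  expect_gt(igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g), 0)

  # sampled-pair network distance never undercuts Hamming distance
  nd <- network_distances(net)
  hm <- orscpop:::hamming(h$sequence)
  expect_true(all(nd >= hm - 1e-9))
})

test_that("star phylogenies are reconstructed exactly", {
  center <- "AAAAA"
  leaves <- c("TAAAA", "ACAAA", "AAGAA", "AAATA", "AAAAC")
  h <- collapse_haplotypes(toy_aln(c(rep(center, 3), leaves)))
  net <- build_network(h)
  expect_equal(nrow(net$edges), 5)
  expect_equal(sum(net$nodes$type == "inferred"), 0)
  deg <- igraph::degree(net$graph)
  expect_equal(unname(sort(deg, decreasing = TRUE)[1]), 5)
  expect_equal(sum(deg == 1), 5)
})

test_that("cpGroup delineation separates distant clusters and refines monotonically", {
  # chain within the limit: one group
  h <- collapse_haplotypes(toy_aln(c("AAAA", "TAAA", "TTAA")))
  net <- build_network(h)
  grp <- delineate_groups(net)
  expect_equal(length(unique(grp$cp_group)), 1)
  expect_false(any(grp$independent))

  # one haplotype 10 steps away at limit 6: independent
  far <- c("AAAAAAAAAA", "TAAAAAAAAA", "TTTTTTTTTT")
  h2 <- collapse_haplotypes(toy_aln(far))
  net2 <- build_network(h2, connection_limit = 6)
  grp2 <- delineate_groups(net2)
  expect_true(grp2$independent[grp2$haplotype ==
                                 h2$haplotype[h2$sequence == "TTTTTTTTTT"]])

  # partitions refine as the threshold decreases
  seqs <- c("AAAAAA", "TAAAAA", "TTTAAA", "TTTTTT")
  h3 <- collapse_haplotypes(toy_aln(seqs))
  net3 <- build_network(h3, connection_limit = 6)
  coarse <- delineate_groups(net3, threshold_limit = 6)
  fine <- delineate_groups(net3, threshold_limit = 1)
  key <- function(g) split(g$haplotype, ifelse(is.na(g$cp_group), g$haplotype, g$cp_group))
  for (blk in key(fine)) {
    parents <- unique(coarse$cp_group[coarse$haplotype %in% blk])
    expect_lte(length(parents), 1)
  }
})

test_that("simulated founder clades are recovered as cpGroups", {
  cfg <- sim_config(K = 6, n_per_group = 8, n_admixed = 0, n_snps = 60,
                    seed = 23, theta_cp = 4, n_cp_sites = 40,
                    species_probs = 0.5)
  s <- simulate_structured_genotypes(cfg)
  aln <- simulate_chloroplast(cfg, s$truth, p_intermediate = 0,
                              extra_step_probs = c(0.3, 0.5, 0.2))
  haps <- collapse_haplotypes(aln)
  net <- build_network(haps, connection_limit = 6)
  grp <- delineate_groups(net)
  asg <- cp_group_assignments(aln, haps, grp)
  asg$subpop <- aln$alleles$group[match(asg$accession_id, aln$alleles$accession_id)]
  ing <- asg[asg$subpop != "outgroup", ]
  # every nuclear group maps to exactly one cpGroup and vice versa
  tab <- table(ing$subpop, ing$cp_group, useNA = "ifany")
  expect_equal(sum(tab > 0), 6)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) <= 1))
  # outgroups stay unconnected to any in-group clade
  outg <- asg[asg$subpop == "outgroup", ]
  expect_true(all(is.na(outg$cp_group) |
                    !(outg$cp_group %in% ing$cp_group)))
})

test_that("ancestral/derived calling follows the outgroup >65% rule", {
  a <- toy_aln(c(o1 = "AA", o2 = "AA", i1 = "AG", i2 = "GG", i3 = "AA"),
               groups = c("outgroup", "outgroup", "W1", "W1", "W2"))
  # per-accession site vectors: site1 alleles A/A/A/G/A, site2 A/A/G/G/A
  cls <- classify_ancestral_derived(a)
  expect_equal(cls$status, c("resolved", "resolved"))
  expect_equal(cls$ancestral, c("A", "A"))
  expect_equal(cls$derived, c("G", "G"))

  # outgroups split 60/40: below the 65% rule -> unresolved
  b <- toy_aln(c(o1 = "A", o2 = "A", o3 = "A", o4 = "G", o5 = "G",
                 i1 = "A", i2 = "G"),
               groups = c(rep("outgroup", 5), "W1", "W1"))
  expect_equal(classify_ancestral_derived(b)$status, "unresolved")

  # monomorphic site -> unresolved, not an error
  c_aln <- toy_aln(c(o = "T", i = "T"), groups = c("outgroup", "W1"))
  expect_equal(classify_ancestral_derived(c_aln)$status, "unresolved")

  expect_error(classify_ancestral_derived(
    toy_aln(c("A", "G"), groups = c("W1", "W1"))), "no outgroup")
})

test_that("the deletion analog and its nested SNP are polarized as constructed", {
  cfg <- sim_config(K = 6, n_per_group = 10, n_admixed = 0, n_snps = 60,
                    seed = 29, theta_cp = 3, species_probs = 0.5)
  s <- simulate_structured_genotypes(cfg)
  aln <- simulate_chloroplast(cfg, s$truth)
  tr <- attr(aln, "cp_truth")
  cls <- classify_ancestral_derived(aln)
  ind <- cls[cls$site_id == tr$indel_site, ]
  nst <- cls[cls$site_id == tr$nested_site, ]
  expect_equal(ind$status, "resolved")
  expect_equal(ind$ancestral, "N")   # non-deletion ancestral
  expect_equal(ind$derived, "D")
  expect_equal(nst$status, "resolved")
  expect_equal(nst$ancestral, "A")
  expect_equal(nst$derived, "G")
})
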