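#' Simulation configuration for structured rice-like panels
#'
#' Bundles the knobs of the synthetic panel generator. Defaults mirror a
#' diversity panel of the wild-rice species complex: six subpopulations,
#' 215 pure accessions plus 71 Dirichlet-admixed ones (286 total, ~25 %
#' planted admixed; the smallest group has 12 accessions), ~28 % missing
#' genotype calls, and twelve chromosomes with rice-like lengths
#' (23-45 Mb).
#'
#' @param K Number of subpopulations.
#' @param fst_targets Per-group Balding-Nichols differentiation F in (0,1)
#'   (recycled to length `K`).
#' @param n_per_group Accessions per pure group (length `K`).
#' @param n_admixed Number of Dirichlet-admixed accessions.
#' @param n_snps Total SNP count across the genome.
#' @param chrom_lengths Twelve chromosome lengths in bp.
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param seed Integer seed; identical configs give identical output.
#' @param theta_cp Chloroplast mutation steps from the root to each group
#'   founder haplotype.
#' @param n_cp_sites Number of polymorphic chloroplast sites.
#' @param recomb_block_bp Scale (bp) of the block-mosaic linkage model;
#'   `0` (the default) draws SNPs independently, giving exact
#'   Balding-Nichols marginals.
#' @param n_founder_haps Founder haplotypes per group pool when
#'   `recomb_block_bp > 0`.
#' @param species_probs Per-group probability that an accession carries the
#'   perennial species label (`O. rufipogon`) rather than the annual one
#'   (`O. nivara`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(K = 6,
                       fst_targets = 0.3,
                       n_per_group = c(60, 40, 25, 40, 12, 38),
                       n_admixed = 71,
                       n_snps = 5000,
                       chrom_lengths = rice_chrom_lengths(),
                       missing_rate = 0.28,
                       seed = 1,
                       theta_cp = 3,
                       n_cp_sites = 25,
                       recomb_block_bp = 0,
                       n_founder_haps = 8,
                       species_probs = c(0.91, 0.44, 1.00, 0.36, 0.17, 0.50)) {
  fst_targets <- rep_len(fst_targets, K)
  n_per_group <- rep_len(n_per_group, K)
  species_probs <- rep_len(species_probs, K)
  stopifnot(K >= 1, all(n_per_group > 0), n_admixed >= 0, n_snps > 0,
            length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            missing_rate >= 0, missing_rate < 1,
            all(fst_targets >= 0), all(fst_targets < 1),
            n_cp_sites >= 5, theta_cp >= 0, recomb_block_bp >= 0)
  structure(list(K = K, fst_targets = fst_targets, n_per_group = n_per_group,
                 n_admixed = n_admixed, n_snps = n_snps,
                 chrom_lengths = chrom_lengths, missing_rate = missing_rate,
                 seed = as.integer(seed), theta_cp = theta_cp,
                 n_cp_sites = n_cp_sites, recomb_block_bp = recomb_block_bp,
                 n_founder_haps = n_founder_haps,
                 species_probs = species_probs),
            class = "sim_config")
}

#' Rice-like chromosome lengths (bp)
#'
#' Twelve lengths between 23 and 45 Mb, matching the geometry of the rice
#' nuclear genome so that window and LD analyses see realistic coordinates.
#' @export
rice_chrom_lengths <- function() {
  stats::setNames(
    as.integer(c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                 29.7, 28.4, 23.0, 23.2, 28.5, 27.5) * 1e6),
    as.character(1:12)
  )
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a structured diploid SNP panel (Balding-Nichols)
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); each group's
#' frequency is Beta-distributed around the ancestral value with the
#' group's differentiation parameter F (`F = 0` collapses to a point mass).
#' Pure accessions draw dosages Binomial(2, group frequency); admixed
#' accessions get symmetric Dirichlet(1) ancestry and draw each allele from
#' a group sampled by ancestry. SNP positions are uniform over the
#' chromosomes; missingness is applied uniformly at `missing_rate`. With
#' `recomb_block_bp > 0` each group instead carries a finite pool of
#' founder haplotypes and individual chromosomes are block mosaics of the
#' pool (exponential block lengths), which induces r-squared decay on the
#' `recomb_block_bp` scale.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genotypes` (a `geno_tbl`), `metadata` (accession
#'   tibble: id, species label, planted `subpop` — `"admixed"` for
#'   Dirichlet accessions), and `truth` (list: `true_q` ancestry tibble,
#'   `true_fst`, `group_freqs`, group labels).
#' @export
simulate_structured_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    K <- cfg$K
    groups <- paste0("W", seq_len(K))
    n_pure <- cfg$n_per_group
    n_adm <- cfg$n_admixed
    n_tot <- sum(n_pure) + n_adm
    S <- cfg$n_snps

    # genomic positions: counts per chromosome proportional to length
    chr_names <- names(cfg$chrom_lengths)
    if (is.null(chr_names)) chr_names <- as.character(seq_along(cfg$chrom_lengths))
    counts <- as.vector(stats::rmultinom(1, S, prob = cfg$chrom_lengths))
    chrom <- rep(chr_names, counts)
    pos <- unlist(lapply(seq_along(counts), function(i) {
      sort(sample.int(cfg$chrom_lengths[i], counts[i]))
    }), use.names = FALSE)
    ord <- order(chrom, pos)   # as_geno sorts chrom as character
    chrom <- chrom[ord]; pos <- pos[ord]

    p_anc <- stats::runif(S, 0.05, 0.95)
    freq <- matrix(NA_real_, S, K)
    for (k in seq_len(K)) {
      f <- cfg$fst_targets[k]
      freq[, k] <- if (f == 0) p_anc else
        stats::rbeta(S, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }

    # ancestry: pure accessions are indicators, admixed are Dirichlet(1)
    q <- matrix(0, n_tot, K)
    grp_of <- rep(NA_character_, n_tot)
    i <- 1
    for (k in seq_len(K)) {
      idx <- i:(i + n_pure[k] - 1)
      q[idx, k] <- 1
      grp_of[idx] <- groups[k]
      i <- i + n_pure[k]
    }
    if (n_adm > 0) {
      idx <- i:n_tot
      q[idx, ] <- rdirichlet(n_adm, rep(1, K))
      grp_of[idx] <- "admixed"
    }
    ids <- sprintf("%s_%03d", grp_of, stats::ave(seq_len(n_tot), grp_of, FUN = seq_along))

    calls <- if (cfg$recomb_block_bp > 0) {
      mosaic_calls(freq, q, chrom, pos, cfg)
    } else {
      iid_calls(freq, q)
    }
    if (cfg$missing_rate > 0) {
      calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
    }
    colnames(calls) <- ids

    species <- ifelse(
      stats::runif(n_tot) < as.vector(q %*% cfg$species_probs),
      "O. rufipogon", "O. nivara")

    sites <- tibble::tibble(
      snp_id = sprintf("S%05d", seq_len(S)), chrom = chrom, pos = pos,
      ref = sample(c("A", "C", "G", "T"), S, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), S, replace = TRUE))
    swap <- sites$ref == sites$alt
    sites$alt[swap] <- chartr("ACGT", "CGTA", sites$ref[swap])

    metadata <- tibble::tibble(
      accession_id = ids, species_label = species,
      country = NA_character_, latitude = NA_real_, longitude = NA_real_,
      subpop = grp_of, cp_group = NA_character_,
      hull_color = NA_character_, pericarp_score = NA_real_,
      rc_indel = NA_character_, bh4_indel = NA_character_)

    truth <- list(true_q = as_ancestry(q, ids, groups),
                  true_fst = stats::setNames(cfg$fst_targets, groups),
                  group_freqs = freq, groups = groups,
                  introgressed_ids = character(0))
    list(genotypes = geno_from_matrix(sites, calls), metadata = metadata,
         truth = truth)
  })
}

# independent-SNP dosages: SNP x accession integer matrix
iid_calls <- function(freq, q) {
  S <- nrow(freq); n <- nrow(q); K <- ncol(q)
  calls <- matrix(NA_integer_, S, n)
  pure <- which(rowSums(q == 1) == 1)
  for (i in pure) {
    k <- which(q[i, ] == 1)
    calls[, i] <- stats::rbinom(S, 2, freq[, k])
  }
  for (i in setdiff(seq_len(n), pure)) {
    g1 <- sample.int(K, S, replace = TRUE, prob = q[i, ])
    g2 <- sample.int(K, S, replace = TRUE, prob = q[i, ])
    calls[, i] <- stats::rbinom(S, 1, freq[cbind(seq_len(S), g1)]) +
      stats::rbinom(S, 1, freq[cbind(seq_len(S), g2)])
  }
  calls
}

# block-mosaic dosages: each group owns a pool of founder haplotypes; a
# gamete copies one pool haplotype per exponential-length block
mosaic_calls <- function(freq, q, chrom, pos, cfg) {
  S <- nrow(freq); n <- nrow(q); K <- ncol(q)
  H <- cfg$n_founder_haps
  pool <- lapply(seq_len(K), function(k) {
    matrix(stats::rbinom(S * H, 1, freq[, k]), S, H)
  })
  block_of <- function() {
    # per-gamete block index along the genome
    b <- integer(S); cur <- 1L
    next_break <- pos[1] + stats::rexp(1, 1 / cfg$recomb_block_bp)
    last_chr <- chrom[1]
    for (s in seq_len(S)) {
      if (chrom[s] != last_chr || pos[s] > next_break) {
        cur <- cur + 1L
        next_break <- pos[s] + stats::rexp(1, 1 / cfg$recomb_block_bp)
        last_chr <- chrom[s]
      }
      b[s] <- cur
    }
    b
  }
  gamete <- function(qi) {
    b <- block_of()
    nb <- max(b)
    grp <- sample.int(K, nb, replace = TRUE, prob = qi)[b]
    hap <- sample.int(H, nb, replace = TRUE)[b]
    idx <- cbind(seq_len(S), hap)
    out <- integer(S)
    for (k in unique(grp)) {
      sel <- grp == k
      out[sel] <- pool[[k]][idx[sel, , drop = FALSE]]
    }
    out
  }
  calls <- matrix(NA_integer_, S, n)
  for (i in seq_len(n)) calls[, i] <- gamete(q[i, ]) + gamete(q[i, ])
  calls
}

#' Place accessions on a map consistent with their ancestry
#'
#' Each subpopulation receives a centroid drawn around a common base point
#' with standard deviation `centroid_spread_km`; pure accessions scatter
#' around their group centroid with `jitter_km`, and admixed accessions sit
#' at the ancestry-weighted average of the centroids (plus jitter), so that
#' geography is correlated with ancestry as in a species-wide collection.
#'
#' @param metadata Accession tibble with a `subpop` column.
#' @param truth Truth list from [simulate_structured_genotypes()] (uses
#'   `true_q` for admixed placement).
#' @param centroid_spread_km Spread of group centroids (km).
#' @param jitter_km Within-group scatter (km).
#' @param seed Integer seed.
#' @param base Latitude/longitude of the region center (default 20N 100E,
#'   continental SE Asia).
#' @return `metadata` with `latitude`/`longitude` filled in.
#' @export
simulate_geography <- function(metadata, truth, centroid_spread_km = 2000,
                               jitter_km = 100, seed = 1,
                               base = c(lat = 20, lon = 100)) {
  stopifnot("subpop" %in% names(metadata))
  with_seed(seed, {
    groups <- truth$groups
    K <- length(groups)
    km_per_deg <- 111.32
    cen <- cbind(lat = base[["lat"]] + stats::rnorm(K, 0, centroid_spread_km / km_per_deg),
                 lon = base[["lon"]] + stats::rnorm(K, 0, centroid_spread_km / km_per_deg))
    qm <- ancestry_matrix(truth$true_q)[metadata$accession_id, , drop = FALSE]
    latlon <- qm %*% cen
    n <- nrow(metadata)
    metadata$latitude <- pmax(-89, pmin(89,
      latlon[, "lat"] + stats::rnorm(n, 0, jitter_km / km_per_deg)))
    metadata$longitude <- latlon[, "lon"] + stats::rnorm(n, 0, jitter_km / km_per_deg)
    metadata
  })
}
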