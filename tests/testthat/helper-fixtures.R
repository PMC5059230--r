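# Small in-code fixtures and independent oracles shared across tests.

# build a geno_tbl from a dosage matrix (snp x accession)
toy_geno <- function(dos, chrom = "1", pos = NULL, ref = "A", alt = "G") {
  n_snp <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  if (is.null(colnames(dos))) colnames(dos) <- paste0("acc", seq_len(ncol(dos)))
  as_geno(dplyr::bind_cols(
    tibble::tibble(snp_id = paste0("s", seq_len(n_snp)),
                   chrom = rep_len(chrom, n_snp), pos = pos,
                   ref = rep_len(ref, n_snp), alt = rep_len(alt, n_snp)),
    tibble::as_tibble(dos)))
}

# literal scalar transcription of the Weir-Cockerham (1984) variance
# components for one SNP; pops = list of dosage vectors (NA = missing)
wc_oracle_snp <- function(pops) {
  r <- length(pops)
  n <- vapply(pops, function(x) sum(!is.na(x)), numeric(1))
  p <- vapply(pops, function(x) sum(x, na.rm = TRUE) / (2 * sum(!is.na(x))), numeric(1))
  h <- vapply(pops, function(x) mean(x[!is.na(x)] == 1), numeric(1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# exhaustive pairwise-allele-comparison oracle for per-site diversity:
# mean number of differences over all C(n,2) pairs of called alleles
pi_oracle_site <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)],
                           function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    diffs <- diffs + sum(alleles[i] != alleles[(i + 1):n])
  }
  diffs / choose(n, 2)
}

# exhaustive Mantel p over all permutations (two-sided on |r|)
mantel_oracle <- function(a, b) {
  n <- nrow(a)
  lt <- lower.tri(a)
  r_obs <- stats::cor(a[lt], b[lt])
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) stats::cor(a[lt], b[p, p][lt]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# two-sided Fisher exact p by hypergeometric enumeration on a 2x2 table
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x_obs, m, n, k) * (1 + 1e-7)])
}

chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
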