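#' Chloroplast variant alignments
#'
#' A `cp_aln` holds a complete allele matrix over a small set of
#' polymorphic chloroplast sites: `$alleles` is a tibble with
#' `accession_id`, `group`, then one single-character column per site;
#' `$sites` records each site's id, kind (`SNP` or `indel` — indels are
#' single characters with unit mutational weight), and its ancestral and
#' derived state.
#'
#' @param alleles,sites Tibbles as described above.
#' @return A `cp_aln` object.
#' @export
cp_aln <- function(alleles, sites) {
  alleles <- tibble::as_tibble(alleles)
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("accession_id", "group") %in% names(alleles)),
            all(c("site_id", "kind") %in% names(sites)),
            all(sites$site_id %in% names(alleles)))
  structure(list(alleles = alleles, sites = sites), class = "cp_aln")
}

#' @export
print.cp_aln <- function(x, ...) {
  cat(sprintf("# Chloroplast alignment: %d accessions x %d sites (%d indel)\n",
              nrow(x$alleles), nrow(x$sites), sum(x$sites$kind == "indel")))
  invisible(x)
}

cp_seq_matrix <- function(a) {
  m <- as.matrix(a$alleles[, a$sites$site_id, drop = FALSE])
  rownames(m) <- a$alleles$accession_id
  m
}

#' Simulate chloroplast haplotypes by stepwise mutation from a root
#'
#' Each subpopulation founder haplotype lies `theta_cp` mutational steps
#' from a common root, on a site set disjoint from every other group's
#' walk. Accessions carry either the founder or an intermediate state of
#' their group's walk (with probability `p_intermediate`, including the
#' root itself), plus 0-2 private extra steps. Outgroup accessions lie at
#' least 6 steps from the root. One site is an indel (a 69-bp-deletion
#' analog) and the following site a SNP nested within it; both are placed
#' on group walks so ancestral/derived calling can be checked against the
#' construction.
#'
#' @param cfg A [sim_config()] (`theta_cp`, `n_cp_sites`, `seed`).
#' @param truth Truth list from [simulate_structured_genotypes()].
#' @param p_intermediate Probability that an in-group accession carries an
#'   interior walk state rather than the founder.
#' @param extra_step_probs Probabilities of 0, 1, 2 private extra steps.
#' @param n_outgroups Number of outgroup accessions.
#' @return A `cp_aln`; its `"cp_truth"` attribute records the root, the
#'   founder states, each group's ordered walk sites, and per-accession
#'   walk positions.
#' @export
simulate_chloroplast <- function(cfg, truth, p_intermediate = 0.25,
                                 extra_step_probs = c(0.7, 0.25, 0.05),
                                 n_outgroups = 3) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_cp_sites >= 5)
  K <- length(truth$groups)
  S <- cfg$n_cp_sites
  theta <- cfg$theta_cp
  if (K * theta > S) {
    stop("requested ", K * theta, " walk steps exceed ", S, " sites", call. = FALSE)
  }
  with_seed(cfg$seed + 101L, {
    site_id <- sprintf("cp%02d", seq_len(S))
    kind <- rep("SNP", S)
    indel_site <- min(6L, S)
    nested_site <- min(7L, S)
    kind[indel_site] <- "indel"
    anc <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    der <- unname(vapply(anc, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), ""))
    anc[indel_site] <- "N"; der[indel_site] <- "D"
    anc[nested_site] <- "A"; der[nested_site] <- "G"
    sites <- tibble::tibble(site_id = site_id, kind = kind,
                            ancestral = anc, derived = der)

    # disjoint walk site sets; pin the indel analog and nested SNP on walks
    pool <- sample(setdiff(seq_len(S), c(indel_site, nested_site)))
    walks <- vector("list", K)
    if (theta > 0) {
      for (k in seq_len(K)) {
        need <- theta
        w <- integer(0)
        if (k == min(2L, K)) { w <- indel_site; need <- need - 1 }
        if (k == K && need > 0) { w <- c(w, nested_site); need <- need - 1 }
        if (need > 0) { w <- c(w, pool[seq_len(need)]); pool <- pool[-seq_len(need)] }
        walks[[k]] <- sample(w)   # random step order
      }
    } else {
      walks <- rep(list(integer(0)), K)
    }
    spare <- setdiff(seq_len(S), c(unlist(walks), indel_site, nested_site))

    root <- anc
    founder_of <- function(w) { h <- root; h[w] <- der[w]; h }
    founders <- t(vapply(walks, founder_of, root))
    rownames(founders) <- truth$groups

    qm <- ancestry_matrix(truth$true_q)
    ids <- rownames(qm)
    grp <- unname(ifelse(apply(qm, 1, max) == 1,
                         truth$groups[max.col(qm)], "admixed"))
    n <- length(ids)
    walk_pos <- integer(n)
    hap <- matrix(root, n, S, byrow = TRUE)
    for (i in seq_len(n)) {
      k <- if (grp[i] == "admixed") {
        sample.int(K, 1, prob = qm[i, ])
      } else {
        match(grp[i], truth$groups)
      }
      j <- if (theta == 0 || stats::runif(1) >= p_intermediate) theta
           else sample.int(theta, 1) - 1L   # 0 .. theta-1, root included
      walk_pos[i] <- j
      w <- walks[[k]]
      if (j > 0) hap[i, w[seq_len(j)]] <- der[w[seq_len(j)]]
      e <- sample.int(3, 1, prob = extra_step_probs) - 1L
      if (e > 0 && length(spare) > 0) {
        es <- sample(spare, min(e, length(spare)))
        hap[i, es] <- der[es]
      }
    }

    out_ids <- character(0)
    if (n_outgroups > 0) {
      # one step borrowed from each group walk (round-robin), then private
      # spares, so outgroups sit >= 6 steps from the root but far from any
      # in-group haplotype; the indel analog and its nested SNP stay
      # ancestral in outgroups so polarity remains recoverable
      shared <- unlist(lapply(walks, function(w) {
        w <- setdiff(w, c(indel_site, nested_site))
        w[1]
      }))
      shared <- shared[!is.na(shared)]
      og <- matrix(root, n_outgroups, S, byrow = TRUE)
      out_ids <- sprintf("OUT_%02d", seq_len(n_outgroups))
      avail <- unique(c(shared, spare))
      for (i in seq_len(n_outgroups)) {
        w <- avail[seq_len(min(6 + i - 1, length(avail)))]
        og[i, w] <- der[w]
      }
      hap <- rbind(hap, og)
      grp <- c(grp, rep("outgroup", n_outgroups))
      walk_pos <- c(walk_pos, rep(NA_integer_, n_outgroups))
      ids <- c(ids, out_ids)
    }

    colnames(hap) <- site_id
    aln <- cp_aln(dplyr::bind_cols(
      tibble::tibble(accession_id = ids, group = grp),
      tibble::as_tibble(hap)), sites)
    attr(aln, "cp_truth") <- list(
      root = stats::setNames(root, site_id),
      founders = founders,
      walks = lapply(walks, function(w) site_id[w]),
      walk_pos = stats::setNames(walk_pos, ids),
      outgroup_ids = out_ids,
      indel_site = site_id[indel_site], nested_site = site_id[nested_site])
    aln
  })
}

#' Read/write chloroplast alignments
#'
#' The tabular form is a pair of TSVs: the allele table
#' (`accession_id`, `group`, one column per site) and a site table
#' (`site_id`, `kind`, `ancestral`, `derived`). The FASTA form holds the
#' concatenated single-character site alleles per accession (site kinds
#' default to SNP on read).
#'
#' @param a A `cp_aln`.
#' @param path,sites_path Paths for the allele and site tables.
#' @return `read_cp_alignment()` returns a `cp_aln`.
#' @export
write_cp_alignment <- function(a, path, sites_path = paste0(path, ".sites")) {
  readr::write_tsv(a$alleles, path, progress = FALSE)
  readr::write_tsv(a$sites, sites_path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cp_alignment
#' @export
read_cp_alignment <- function(path, sites_path = paste0(path, ".sites")) {
  alleles <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(.default = "c"))
  sites <- readr::read_tsv(sites_path, show_col_types = FALSE, progress = FALSE)
  cp_aln(alleles, sites)
}

#' @rdname write_cp_alignment
#' @export
write_cp_fasta <- function(a, path) {
  m <- cp_seq_matrix(a)
  seqinr::write.fasta(as.list(apply(m, 1, paste, collapse = "")),
                      names = rownames(m), file.out = path, as.string = TRUE)
  invisible(path)
}

#' @rdname write_cp_fasta
#' @param groups Optional named character vector of group labels per
#'   accession (defaults to `"unknown"`).
#' @export
read_cp_fasta <- function(path, groups = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  ids <- names(fa)
  seqs <- toupper(unlist(fa, use.names = FALSE))
  m <- do.call(rbind, strsplit(seqs, ""))
  colnames(m) <- sprintf("cp%02d", seq_len(ncol(m)))
  grp <- if (is.null(groups)) rep("unknown", length(ids)) else unname(groups[ids])
  cp_aln(
    dplyr::bind_cols(tibble::tibble(accession_id = ids, group = grp),
                     tibble::as_tibble(m)),
    tibble::tibble(site_id = colnames(m), kind = "SNP",
                   ancestral = NA_character_, derived = NA_character_))
}
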