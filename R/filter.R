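#' Filter SNPs on call rate and minor allele count
#'
#' Retains SNPs whose per-SNP call rate across the accessions in `g` is
#' strictly greater than `min_call_rate`, and whose minor allele count
#' (counted over called alleles only) is at least `min_mac`. The defaults
#' reproduce the GBS panel filter: call rate > 50 % and MAC > 3
#' (i.e. MAC >= 4). Retained SNPs keep their order; the removal counts per
#' rule are attached as the `"removed"` attribute and reported in a message.
#'
#' @param g A `geno_tbl`.
#' @param min_call_rate Fraction of accessions that must be called
#'   (exclusive bound). Default 0.5.
#' @param min_mac Minimum minor allele count (inclusive). Default 4.
#' @param quiet Suppress the per-rule removal message.
#' @return The filtered `geno_tbl`.
#' @export
filter_snps <- function(g, min_call_rate = 0.5, min_mac = 4, quiet = FALSE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_mac >= 0)
  g <- as_geno(g)
  m <- geno_calls(g)
  n_acc <- ncol(m)
  called <- !is.na(m)
  call_rate <- rowSums(called) / n_acc
  alt <- rowSums(m, na.rm = TRUE)
  total <- 2L * rowSums(called)
  mac <- pmin(alt, total - alt)
  keep_cr <- call_rate > min_call_rate
  keep_mac <- mac >= min_mac
  removed <- c(call_rate = sum(!keep_cr), mac = sum(keep_cr & !keep_mac))
  out <- g[keep_cr & keep_mac, ]
  class(out) <- class(g)
  if (!quiet) {
    message(sprintf("filter_snps: removed %d SNP(s) on call rate, %d on MAC; %d retained",
                    removed[["call_rate"]], removed[["mac"]], nrow(out)))
  }
  if (nrow(out) == 0) warning("no SNPs retained after filtering", call. = FALSE)
  attr(out, "removed") <- removed
  out
}
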