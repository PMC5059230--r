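#' Genotype tables
#'
#' A genotype table (`geno_tbl`) is a tibble with one row per SNP and the
#' columns `snp_id`, `chrom`, `pos`, `ref`, `alt`, followed by one integer
#' dosage column per accession. Dosages count copies of the alternate allele
#' (`0`, `1`, `2`); missing calls are `NA`. Rows are kept sorted by
#' `(chrom, pos)`, positions are 1-based, and heterozygotes are dosage 1
#' regardless of phase.
#'
#' @param x A data frame with the columns described above.
#' @return `as_geno()` returns a validated `geno_tbl`;
#'   `geno_calls()` a SNP x accession integer matrix (rownames = `snp_id`);
#'   `geno_sites()` the five SNP metadata columns as a tibble;
#'   `geno_accessions()` a character vector of accession ids.
#' @examples
#' g <- as_geno(tibble::tibble(
#'   snp_id = c("s1", "s2"), chrom = c("1", "1"), pos = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"), acc1 = c(0L, 2L), acc2 = c(1L, NA)
#' ))
#' geno_calls(g)
#' @export
as_geno <- function(x) {
  x <- tibble::as_tibble(x)
  meta <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(meta, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$snp_id)) {
    dup <- unique(x$snp_id[duplicated(x$snp_id)])
    stop("duplicate snp_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  acc <- setdiff(names(x), meta)
  if (anyDuplicated(acc)) stop("duplicate accession ids", call. = FALSE)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  for (a in acc) {
    v <- x[[a]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      stop("dosages must be 0, 1, 2 or NA (column ", a, ")", call. = FALSE)
    }
    x[[a]] <- as.integer(v)
  }
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  class(x) <- c("geno_tbl", class(tibble::tibble()))
  x
}

#' @rdname as_geno
#' @export
geno_accessions <- function(x) {
  setdiff(names(x), c("snp_id", "chrom", "pos", "ref", "alt"))
}

#' @rdname as_geno
#' @export
geno_sites <- function(x) {
  tibble::as_tibble(x)[, c("snp_id", "chrom", "pos", "ref", "alt")]
}

#' @rdname as_geno
#' @export
geno_calls <- function(x) {
  acc <- geno_accessions(x)
  m <- as.matrix(tibble::as_tibble(x)[, acc, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$snp_id
  m
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf("# Genotype table: %d SNPs x %d accessions, %d chromosome(s)\n",
              nrow(x), length(geno_accessions(x)),
              length(unique(x$chrom))))
  NextMethod()
}

#' @rdname as_geno
#' @param g A `geno_tbl`.
#' @param ids Accession ids to keep.
#' @export
geno_subset <- function(g, ids) {
  stopifnot(all(ids %in% geno_accessions(g)))
  out <- tibble::as_tibble(g)[, c("snp_id", "chrom", "pos", "ref", "alt", ids)]
  class(out) <- class(g)
  out
}

# rebuild a geno_tbl from a sites tibble and a call matrix
geno_from_matrix <- function(sites, calls) {
  stopifnot(nrow(sites) == nrow(calls))
  as_geno(dplyr::bind_cols(sites, tibble::as_tibble(calls)))
}
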