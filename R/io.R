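#' Read diploid SNP genotypes from VCF or a hapmap-style dosage table
#'
#' Loads a biallelic diploid SNP set into a [as_geno()] genotype table.
#' Multi-allelic VCF sites are dropped (with a message giving the count);
#' phase is ignored and heterozygotes become dosage 1. Sites are sorted by
#' `(chrom, pos)` on load.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a tab-separated dosage
#'   table with columns `snp_id, chrom, pos, ref, alt` then one dosage
#'   column per accession (`NA` = missing).
#' @param format `"vcf"` or `"table"`; guessed from the file extension by
#'   default.
#' @return A `geno_tbl` tibble.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_table(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf))
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path, call. = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic site(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  called <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[called] <- (a1[called] == "1") + (a2[called] == "1")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  as_geno(dplyr::bind_cols(
    tibble::tibble(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT),
    tibble::as_tibble(dos)
  ))
}

read_genotypes_table <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  as_geno(x)
}

#' Write a genotype table to disk
#'
#' @param g A `geno_tbl`.
#' @param path Output path. VCF output is bgzip-compressed when `path` ends
#'   in `.gz`.
#' @param format `"vcf"` or `"table"` (tab-separated dosage table).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("auto", "vcf", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  g <- as_geno(g)
  if (format == "table") {
    readr::write_tsv(tibble::as_tibble(g), path, na = "NA", progress = FALSE)
    return(invisible(path))
  }
  acc <- geno_accessions(g)
  dos <- geno_calls(g)
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt_chr[is.na(dos)] <- "./."
  colnames(gt_chr) <- acc
  fix <- cbind(CHROM = g$chrom, POS = as.character(g$pos), ID = g$snp_id,
               REF = g$ref, ALT = g$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               paste0("##contig=<ID=", unique(g$chrom), ">"),
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix,
                      gt = cbind(FORMAT = "GT", gt_chr))
  # vcfR::write.vcf always emits gzip; write plain text through its lines when
  # an uncompressed .vcf was requested
  tmp <- if (grepl("\\.gz$", path)) path else paste0(path, ".gz")
  vcfR::write.vcf(vcf, tmp)
  if (tmp != path) {
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
    unlink(tmp)
  }
  invisible(path)
}

#' Read an accession metadata table
#'
#' Tab-separated, one row per accession, columns `accession_id,
#' species_label, country, latitude, longitude, subpop, cp_group,
#' hull_color, pericarp_score, rc_indel, bh4_indel`. Unknown species labels
#' are kept verbatim; empty latitude/longitude mean unknown collection site
#' and are accepted as `NA`. Coordinates and pericarp scores are validated.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, na = c("NA", ""), show_col_types = FALSE, progress = FALSE)
  validate_metadata(x)
}

validate_metadata <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"accession_id" %in% names(x)) stop("metadata lacks accession_id", call. = FALSE)
  if (anyDuplicated(x$accession_id)) {
    stop("duplicate accession_id: ",
         paste(unique(x$accession_id[duplicated(x$accession_id)]), collapse = ", "),
         call. = FALSE)
  }
  check_range <- function(col, lo, hi) {
    if (!col %in% names(x)) return()
    bad <- which(!is.na(x[[col]]) & (x[[col]] < lo | x[[col]] > hi))
    if (length(bad) > 0) {
      stop(col, " out of [", lo, ", ", hi, "] for accession(s): ",
           paste(x$accession_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  check_range("latitude", -90, 90)
  check_range("longitude", -180, 180)
  check_range("pericarp_score", 0, 1)
  x
}

#' @rdname read_metadata
#' @param x Metadata tibble to write.
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(validate_metadata(x), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read an ancestry (Q) matrix in fastStructure meanQ layout
#'
#' Whitespace-separated ancestry proportions, one row per accession, one
#' column per group, no header. Rows whose sum is within `1e-3` of 1 are
#' renormalized to sum exactly 1; larger deviations are an error.
#'
#' @param path Path to the meanQ-style file.
#' @param labels Character vector of accession ids, one per row.
#' @return A tibble with `accession_id` and ancestry columns `Q1..QK`.
#' @export
read_qmatrix <- function(path, labels) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(m)) stop("non-numeric entries in Q matrix: ", path, call. = FALSE)
  if (nrow(m) != length(labels)) {
    stop("Q matrix has ", nrow(m), " rows but ", length(labels), " labels",
         call. = FALSE)
  }
  if (ncol(m) < 2) stop("Q matrix needs at least 2 ancestry columns", call. = FALSE)
  as_ancestry(m, labels)
}

as_ancestry <- function(m, labels, group_names = paste0("Q", seq_len(ncol(m)))) {
  if (any(m < 0 | m > 1)) stop("ancestry proportions must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-3)
  if (length(bad) > 0) {
    stop("ancestry row(s) not summing to 1 (tolerance 1e-3): row ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  m <- m / rs
  colnames(m) <- group_names
  dplyr::bind_cols(tibble::tibble(accession_id = labels), tibble::as_tibble(m))
}

#' @rdname read_qmatrix
#' @param q Ancestry tibble (as returned by `read_qmatrix()`).
#' @export
write_qmatrix <- function(q, path) {
  m <- as.matrix(q[setdiff(names(q), "accession_id")])
  utils::write.table(format(m, digits = 8, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ancestry_matrix <- function(q) {
  m <- as.matrix(q[setdiff(names(q), "accession_id")])
  rownames(m) <- q$accession_id
  m
}
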