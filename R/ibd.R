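#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km (via \pkg{geosphere}).
#' Accessions without coordinates cannot be placed and should be dropped
#' before building distance matrices (see [geo_dist_matrix()]).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km; `NA` where any coordinate is missing.
#' @examples
#' geo_distance(0, 0, 0, 90)  # quarter great circle, ~10007.5 km
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  out <- rep(NA_real_, n)
  ok <- !(is.na(lat1) | is.na(lon1) | is.na(lat2) | is.na(lon2))
  if (any(ok)) {
    out[ok] <- geosphere::distHaversine(
      cbind(lon1, lat1)[ok, , drop = FALSE],
      cbind(lon2, lat2)[ok, , drop = FALSE], r = 6371)
  }
  out
}

#' Pairwise geographic distance matrix from metadata
#'
#' Accessions with missing coordinates are excluded (with a message), as
#' collections without location detail cannot enter an
#' isolation-by-distance test.
#'
#' @param metadata Tibble with `accession_id`, `latitude`, `longitude`.
#' @return A symmetric km matrix over the located accessions.
#' @export
geo_dist_matrix <- function(metadata) {
  located <- !is.na(metadata$latitude) & !is.na(metadata$longitude)
  if (any(!located)) {
    message(sum(!located), " accession(s) without coordinates excluded")
  }
  md <- metadata[located, ]
  n <- nrow(md)
  m <- matrix(0, n, n, dimnames = list(md$accession_id, md$accession_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    m[i, j] <- m[j, i] <- geo_distance(md$latitude[i], md$longitude[i],
                                       md$latitude[j], md$longitude[j])
  }
  m
}

#' Mantel test of matrix correlation (isolation by distance)
#'
#' Pearson correlation `r` of the lower triangles of two distance
#' matrices, with a permutation null obtained by jointly permuting the
#' rows and columns of the second matrix. The p-value uses the add-one
#' correction `p = (#{|r*| >= |r|} + 1) / (n_perm + 1)`; `sided = "greater"`
#' counts `r* >= r` instead. Distances can optionally be log-transformed
#' (`log1p`) before correlating.
#'
#' @param genetic,geographic Symmetric matrices with identical labels in
#'   identical order, `n >= 4`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param sided `"two"` (on |r|) or `"greater"`.
#' @param log_dist Log-transform the geographic distances first.
#' @return A `mantel_ibd` object: `r`, `r2`, `p`, `n`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 1000, seed = 1,
                        sided = c("two", "greater"), log_dist = FALSE) {
  sided <- match.arg(sided)
  stopifnot(nrow(genetic) == ncol(genetic),
            all(dim(genetic) == dim(geographic)))
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic)) &&
      !identical(rownames(genetic), rownames(geographic))) {
    stop("matrix labels differ or are ordered differently", call. = FALSE)
  }
  n <- nrow(genetic)
  if (n < 4) stop("Mantel test needs at least 4 observations", call. = FALSE)
  if (log_dist) geographic <- log1p(geographic)
  lt <- lower.tri(genetic)
  x <- genetic[lt]
  y <- geographic[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate distance matrix: zero variance in lower triangle", call. = FALSE)
  }
  r_obs <- stats::cor(x, y)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(x, geographic[p, p][lt])
    }, numeric(1))
  })
  hits <- if (sided == "two") sum(abs(r_perm) >= abs(r_obs)) else sum(r_perm >= r_obs)
  structure(list(r = r_obs, r2 = r_obs^2, p = (hits + 1) / (n_perm + 1),
                 n = n, n_perm = n_perm, sided = sided,
                 r_perm = r_perm), class = "mantel_ibd")
}

#' @export
print.mantel_ibd <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (r2 = %.4f), p = %.4g (%s-sided, %d permutations, n = %d)\n",
              x$r, x$r2, x$p, x$sided, x$n_perm, x$n))
  invisible(x)
}
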