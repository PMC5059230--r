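#' Collapse a chloroplast alignment to haplotypes
#'
#' Accessions with any missing site are excluded (with a message) rather
#' than imputed; identical allele vectors collapse to one haplotype.
#' Haplotypes are numbered `H1, H2, ...` deterministically by descending
#' count, ties broken by sequence lexicographic order.
#'
#' @param a A `cp_aln`.
#' @return A tibble: `haplotype, sequence, count`, one count column per
#'   group (`n_<group>`), and a list-column `accessions`.
#' @export
collapse_haplotypes <- function(a) {
  stopifnot(inherits(a, "cp_aln"))
  m <- cp_seq_matrix(a)
  if (nrow(m) == 0) stop("empty alignment", call. = FALSE)
  complete <- rowSums(is.na(m) | m == "?" | m == "") == 0
  if (any(!complete)) {
    message(sum(!complete), " accession(s) with missing chloroplast sites excluded")
  }
  if (!any(complete)) stop("no accession with complete chloroplast data", call. = FALSE)
  m <- m[complete, , drop = FALSE]
  grp <- a$alleles$group[complete]
  seqs <- unname(apply(m, 1, paste, collapse = ""))
  tab <- tibble::tibble(accession_id = rownames(m), group = grp, sequence = seqs) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = dplyr::n(),
                     accessions = list(.data$accession_id),
                     groups = list(table(.data$group)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::mutate(haplotype = paste0("H", dplyr::row_number()))
  grp_counts <- sort(unique(grp))
  for (gname in grp_counts) {
    tab[[paste0("n_", gname)]] <- vapply(tab$groups, function(t) {
      k <- t[gname]
      if (is.na(k)) 0L else as.integer(k)
    }, integer(1))
  }
  tab$groups <- NULL
  dplyr::relocate(tab, "haplotype", "sequence", "count")
}

hamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Build a statistical-parsimony haplotype network
#'
#' Minimum-spanning-network construction: haplotype pairs are considered
#' in increasing Hamming distance (ties processed together), and a
#' connection is added when the pair's distance does not exceed the
#' connection limit and the pair is not already joined at a network
#' distance less than or equal to its Hamming distance — so equally short
#' alternative connections are all retained, which is what produces loops.
#' A connection of length j introduces j-1 inferred intermediate nodes
#' (private to that connection), every edge being a single mutational
#' step. Haplotype sets farther apart than the limit stay disconnected.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param connection_limit Maximum steps for a connection (default 6,
#'   standing in for the 95-97 % statistical-parsimony limit of a
#'   25-site alignment).
#' @return A `haplo_network`: `nodes` tibble (`node, type, haplotype,
#'   count`), `edges` tibble (`from, to, connection, length`), the
#'   \pkg{igraph} graph, the haplotype table, and the limit.
#' @export
build_network <- function(haps, connection_limit = 6) {
  stopifnot(nrow(haps) >= 1, connection_limit >= 1)
  n <- nrow(haps)
  d <- hamming(haps$sequence)
  nodes <- tibble::tibble(node = haps$haplotype, type = "sampled",
                          haplotype = haps$haplotype, count = haps$count)
  edges <- tibble::tibble(from = character(0), to = character(0),
                          connection = integer(0), length = integer(0))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes$node)
  if (n > 1) {
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    pairs <- pairs[order(d[pairs], pairs[, 1], pairs[, 2]), , drop = FALSE]
    conn_id <- 0L
    inferred <- 0L
    for (dist_level in sort(unique(d[pairs]))) {
      if (dist_level > connection_limit) break
      lvl <- pairs[d[pairs] == dist_level, , drop = FALSE]
      # evaluate against the graph as it stood before this level, so that
      # equally parsimonious alternatives are all retained
      net_d <- igraph::distances(g, v = haps$haplotype, to = haps$haplotype)
      add <- lvl[net_d[lvl] > dist_level, , drop = FALSE]
      for (k in seq_len(nrow(add))) {
        i <- add[k, 1]; j <- add[k, 2]
        conn_id <- conn_id + 1L
        chain <- nodes$node[i]
        if (dist_level > 1) {
          mids <- paste0("m", inferred + seq_len(dist_level - 1))
          inferred <- inferred + dist_level - 1L
          g <- g + igraph::vertices(mids)
          nodes <- dplyr::bind_rows(nodes, tibble::tibble(
            node = mids, type = "inferred", haplotype = NA_character_,
            count = 0L))
          chain <- c(chain, mids)
        }
        chain <- c(chain, nodes$node[j])
        new_e <- tibble::tibble(from = chain[-length(chain)], to = chain[-1],
                                connection = conn_id, length = dist_level)
        edges <- dplyr::bind_rows(edges, new_e)
        g <- igraph::add_edges(g, rbind(new_e$from, new_e$to))
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, graph = g, haplotypes = haps,
                 connection_limit = connection_limit),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  ncomp <- igraph::count_components(x$graph)
  cat(sprintf("Haplotype network: %d sampled + %d inferred nodes, %d connections, %d component(s), limit %d steps\n",
              sum(x$nodes$type == "sampled"), sum(x$nodes$type == "inferred"),
              length(unique(x$edges$connection)), ncomp, x$connection_limit))
  invisible(x)
}

#' Network distance between sampled haplotypes
#'
#' @param net A `haplo_network`.
#' @return Integer matrix of shortest-path step counts (Inf when
#'   disconnected), over sampled haplotype nodes.
#' @export
network_distances <- function(net) {
  s <- net$nodes$node[net$nodes$type == "sampled"]
  igraph::distances(net$graph, v = s, to = s)
}

#' Delineate chloroplast groups at a connection threshold
#'
#' Connections longer than `threshold_limit` steps are removed; connected
#' components with at least two sampled haplotypes become cpGroups
#' (numbered by decreasing total accession count), and sampled singleton
#' components are flagged independent (`NA` group).
#'
#' @param net A `haplo_network`.
#' @param threshold_limit Maximum connection length kept (defaults to the
#'   network's own limit).
#' @return A tibble: `haplotype, cp_group` (`"cpI"`, `"cpII"`, ... or
#'   `NA`), `independent`.
#' @export
delineate_groups <- function(net, threshold_limit = net$connection_limit) {
  keep <- net$edges$length <= threshold_limit
  g2 <- igraph::subgraph_from_edges(
    net$graph, which(keep), delete.vertices = FALSE)
  comp <- igraph::components(g2)$membership
  sampled <- net$nodes$type == "sampled"
  tab <- tibble::tibble(haplotype = net$nodes$node[sampled],
                        count = net$nodes$count[sampled],
                        comp = comp[net$nodes$node[sampled]])
  grp_tab <- tab |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(n_haps = dplyr::n(), total = sum(.data$count),
                     .groups = "drop") |>
    dplyr::filter(.data$n_haps >= 2) |>
    dplyr::arrange(dplyr::desc(.data$total))
  grp_tab$cp_group <- paste0("cp", utils::as.roman(seq_len(nrow(grp_tab))))
  tab |>
    dplyr::left_join(grp_tab[, c("comp", "cp_group")], by = "comp") |>
    dplyr::mutate(independent = is.na(.data$cp_group)) |>
    dplyr::select("haplotype", "cp_group", "independent")
}

#' Classify ancestral vs derived alleles from outgroup frequencies
#'
#' Per site: the allele whose frequency among outgroup accessions exceeds
#' `freq_threshold` and which is also present in the ingroup is called
#' ancestral; the alternative allele is derived. Sites with no such allele
#' (including sites monomorphic overall) are unresolved.
#'
#' @param a A `cp_aln`.
#' @param outgroup_labels Group labels treated as outgroups (default
#'   `"outgroup"`).
#' @param freq_threshold Outgroup frequency that must be exceeded
#'   (default 0.65, i.e. the > 65 % rule).
#' @return A tibble: `site_id, status, ancestral, derived`.
#' @export
classify_ancestral_derived <- function(a, outgroup_labels = "outgroup",
                                       freq_threshold = 0.65) {
  stopifnot(inherits(a, "cp_aln"))
  is_out <- a$alleles$group %in% outgroup_labels
  if (!any(is_out)) stop("no outgroup accessions", call. = FALSE)
  m <- cp_seq_matrix(a)
  res <- lapply(a$sites$site_id, function(s) {
    og <- m[is_out, s]
    ig <- m[!is_out, s]
    og <- og[!is.na(og)]
    tt <- table(og) / length(og)
    anc <- names(tt)[tt > freq_threshold & names(tt) %in% ig]
    if (length(unique(c(og, ig))) < 2 || length(anc) != 1) {
      return(tibble::tibble(site_id = s, status = "unresolved",
                            ancestral = NA_character_, derived = NA_character_))
    }
    der <- setdiff(unique(c(og, ig)), anc)
    tibble::tibble(site_id = s, status = "resolved", ancestral = anc,
                   derived = paste(sort(der), collapse = "/"))
  })
  dplyr::bind_rows(res)
}

#' Assign accessions to chloroplast groups
#'
#' Joins the haplotype of each (complete) accession to the cpGroup
#' delineation.
#'
#' @param a A `cp_aln`.
#' @param haps Output of [collapse_haplotypes()].
#' @param groups Output of [delineate_groups()].
#' @return A tibble: `accession_id, haplotype, cp_group`.
#' @export
cp_group_assignments <- function(a, haps, groups) {
  haps |>
    dplyr::select("haplotype", "accessions") |>
    tidyr::unnest_longer("accessions", values_to = "accession_id") |>
    dplyr::left_join(groups, by = "haplotype") |>
    dplyr::select("accession_id", "haplotype", "cp_group")
}

#' Export a haplotype network
#'
#' Writes the edge list as TSV and the graph as GML (via \pkg{igraph}).
#'
#' @param net A `haplo_network`.
#' @param edge_path,gml_path Output paths (either may be `NULL`).
#' @export
write_network <- function(net, edge_path = NULL, gml_path = NULL) {
  if (!is.null(edge_path)) readr::write_tsv(net$edges, edge_path, progress = FALSE)
  if (!is.null(gml_path)) {
    g <- net$graph
    igraph::V(g)$type <- net$nodes$type[match(igraph::V(g)$name, net$nodes$node)]
    igraph::V(g)$count <- net$nodes$count[match(igraph::V(g)$name, net$nodes$node)]
    igraph::write_graph(g, gml_path, format = "gml")
  }
  invisible(net)
}
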