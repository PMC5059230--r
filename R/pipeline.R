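#' Pipeline configuration
#'
#' Bundles every stage threshold with a simulation config (or input
#' paths). The defaults are the analysis defaults used throughout the
#' package: call rate > 0.5, MAC >= 4, 100-SNP windows, 10-Mb LD cap with
#' 12-accession sub-sampling 100 times, 1000 Mantel permutations, 0.75
#' ancestry threshold, connection limit 6, and the MAF > 0.05 /
#' missing < 3 % / p < 1e-5 SNP selection for the extended-haplotype scan.
#'
#' @param sim A [sim_config()] (inputs are simulated), or `NULL` with
#'   `genotypes`/`metadata`/`qmatrix` paths supplied.
#' @param genotypes,metadata,qmatrix Optional input paths used when `sim`
#'   is `NULL`.
#' @param out_dir Output directory (created); `NULL` returns results
#'   without writing.
#' @param stages Character subset of
#'   `c("filter","assign","fst","pi","dist","tree","ld","mantel","cpnet","domestication","concordance")`.
#' @param min_call_rate,min_mac SNP filter thresholds.
#' @param snps_per_window Window size in SNPs.
#' @param admix_threshold Ancestry assignment threshold.
#' @param ld_n_sub,ld_n_reps,ld_max_dist_bp,ld_bin_edges_bp LD settings.
#' @param n_perm Mantel permutations.
#' @param connection_limit Haplotype-network connection limit (steps).
#' @param maf_min,missing_max,p_cutoff Extended-haplotype SNP selection.
#' @param seed Master seed; per-stage streams are derived as documented in
#'   [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            genotypes = NULL, metadata = NULL, qmatrix = NULL,
                            out_dir = NULL,
                            stages = c("filter", "assign", "fst", "pi", "dist",
                                       "tree", "ld", "mantel", "cpnet",
                                       "domestication", "concordance"),
                            min_call_rate = 0.5, min_mac = 4,
                            snps_per_window = 100, admix_threshold = 0.75,
                            ld_n_sub = 12, ld_n_reps = 100,
                            ld_max_dist_bp = 1e7,
                            ld_bin_edges_bp = seq(0, 1e7, by = 1e6),
                            n_perm = 1000, connection_limit = 6,
                            maf_min = 0.05, missing_max = 0.03,
                            p_cutoff = 1e-5, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> ancestry assignment ->
#' windowed Fst / pi / genetic distance -> NJ tree -> LD decay -> Mantel
#' isolation-by-distance -> chloroplast haplotype network -> domestication
#' introgression scan -> species concordance. Per-stage randomness uses
#' fixed offsets of the master seed (geography +11, LD +12, Mantel +13,
#' bootstrap +14; the simulators use the seed inside `sim`), so stages are
#' individually reproducible. When `out_dir` is set, every stage writes
#' its table(s) plus a `manifest.txt` of resolved parameters and a
#' `summary.json`.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of stage results plus `summary` (named list of headline
#'   numbers).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(cfg$sim)) {
    sim <- stage("simulate", {
      s <- simulate_structured_genotypes(cfg$sim)
      s$metadata <- simulate_geography(s$metadata, s$truth, seed = cfg$seed + 11L)
      s
    })
    g <- sim$genotypes; md <- sim$metadata
    qtbl <- sim$truth$true_q
    say("simulated %d SNPs x %d accessions", nrow(g), length(geno_accessions(g)))
  } else {
    g <- stage("load", read_genotypes(cfg$genotypes))
    md <- stage("load", read_metadata(cfg$metadata))
    qtbl <- if (!is.null(cfg$qmatrix)) {
      stage("load", read_qmatrix(cfg$qmatrix, md$accession_id))
    } else NULL
    sim <- NULL
  }
  want <- function(s) s %in% cfg$stages
  summary <- list(n_snps_raw = nrow(g),
                  n_accessions = length(geno_accessions(g)))

  if (want("filter")) {
    g <- stage("filter", filter_snps(g, cfg$min_call_rate, cfg$min_mac,
                                     quiet = quiet))
    summary$n_snps_filtered <- nrow(g)
    say("filter: %d SNPs retained", nrow(g))
  }

  if (want("assign") && !is.null(qtbl)) {
    asg <- stage("assign", assign_subpop(
      qtbl, group_names = if (!is.null(sim)) sim$truth$groups else NULL,
      threshold = cfg$admix_threshold))
    md$subpop <- asg$subpop[match(md$accession_id, asg$accession_id)]
    res$assignments <- asg
    summary$admixed_fraction <- mean(asg$subpop == "admixed")
    say("assign: %.1f%% admixed", 100 * summary$admixed_fraction)
  }

  pops <- split(md$accession_id, md$subpop)
  pops <- pops[setdiff(names(pops), "admixed")]
  pops <- pops[lengths(pops) >= 2]

  if (want("fst") && length(pops) >= 2) {
    res$fst <- stage("fst", {
      pn <- names(pops)
      fm <- matrix(0, length(pn), length(pn), dimnames = list(pn, pn))
      for (i in seq_along(pn)) {
        for (j in seq_along(pn)[-seq_len(i)]) {
          fm[i, j] <- fm[j, i] <-
            wc_fst(g, pops[c(i, j)], cfg$snps_per_window)$genome
        }
      }
      fm
    })
    summary$mean_pairwise_fst <- mean(res$fst[upper.tri(res$fst)])
    say("fst: mean pairwise %.3f", summary$mean_pairwise_fst)
  }

  if (want("pi")) {
    res$pi <- stage("pi", purrr::imap(pops, function(ids, nm) {
      dplyr::mutate(pi_within(g, ids, cfg$snps_per_window), pop = nm)
    }) |> dplyr::bind_rows())
    summary$mean_pi_per_kb <- mean(res$pi$per_kb, na.rm = TRUE)
  }

  if (want("dist") && length(pops) >= 2) {
    res$dist <- stage("dist", pairwise_distance(g, pops, level = "group"))
  }
  if (want("tree") && !is.null(res$dist) && nrow(res$dist) >= 3) {
    res$tree <- stage("tree", nj_tree(res$dist))
  }

  if (want("ld")) {
    ld_pops <- pops[lengths(pops) >= cfg$ld_n_sub]
    if (length(ld_pops) > 0) {
      res$ld <- stage("ld", subsample_ld(
        g, ld_pops, n_sub = cfg$ld_n_sub, n_reps = cfg$ld_n_reps,
        bin_edges_bp = cfg$ld_bin_edges_bp, max_dist_bp = cfg$ld_max_dist_bp,
        seed = cfg$seed + 12L))
      say("ld: %d populations analysed", length(ld_pops))
    }
  }

  if (want("mantel")) {
    res$mantel <- stage("mantel", {
      located <- md$accession_id[!is.na(md$latitude) & !is.na(md$longitude) &
                                   md$subpop != "admixed"]
      gd <- suppressMessages(geo_dist_matrix(
        md[md$accession_id %in% located, ]))
      gen <- pairwise_distance(g, list(all = located), level = "accession")
      mantel_test(gen[located, located], gd[located, located],
                  n_perm = cfg$n_perm, seed = cfg$seed + 13L)
    })
    summary$mantel_r2 <- res$mantel$r2
    summary$mantel_p <- res$mantel$p
    say("mantel: r2 = %.3f, p = %.3g", res$mantel$r2, res$mantel$p)
  }

  if (want("cpnet") && !is.null(sim)) {
    res$cpnet <- stage("cpnet", {
      aln <- simulate_chloroplast(cfg$sim, sim$truth)
      haps <- collapse_haplotypes(aln)
      net <- build_network(haps, cfg$connection_limit)
      grps <- delineate_groups(net)
      list(alignment = aln, haplotypes = haps, network = net, groups = grps,
           assignments = cp_group_assignments(aln, haps, grps),
           polarity = classify_ancestral_derived(aln))
    })
    summary$n_haplotypes <- nrow(res$cpnet$haplotypes)
    summary$n_cp_groups <- length(unique(stats::na.omit(res$cpnet$groups$cp_group)))
    say("cpnet: %d haplotypes in %d cpGroups", summary$n_haplotypes,
        summary$n_cp_groups)
  }

  if (want("domestication") && !is.null(sim)) {
    res$domestication <- stage("domestication", {
      dom <- simulate_domestication_panel(cfg$sim, sim$truth)
      cult <- dom$metadata$accession_id[dom$metadata$subpop == "sativa"]
      wild_red <- dom$metadata$accession_id[dom$metadata$subpop != "sativa" &
                                              dom$metadata$pericarp_score == 1]
      sel <- select_region_snps(geno_subset(dom$genotypes, cult),
                                geno_subset(dom$genotypes, wild_red),
                                region = dom$truth$region,
                                maf_min = cfg$maf_min,
                                missing_max = cfg$missing_max,
                                p_cutoff = cfg$p_cutoff)
      eh <- build_extended_haplotypes(
        dom$genotypes, sel$snp_id, cult,
        focal_markers = c(dom$truth$focal_snp_ids, dom$truth$indel_id))
      calls <- classify_introgression(eh)
      list(panel = dom, selected = sel, haplotypes = calls,
           pheno = phenotype_genotype_concordance(dom$metadata))
    })
    cls <- res$domestication$haplotypes
    wild_ids <- res$domestication$panel$metadata$accession_id[
      res$domestication$panel$metadata$subpop != "sativa"]
    flagged <- cls$accession_id[cls$classification == "introgressed" &
                                  cls$accession_id %in% wild_ids]
    summary$n_selected_snps <- nrow(res$domestication$selected)
    summary$n_introgressed_called <- length(flagged)
    say("domestication: %d SNPs selected, %d wild accessions called introgressed",
        summary$n_selected_snps, summary$n_introgressed_called)
  }

  if (want("concordance") && !is.null(res$assignments)) {
    res$concordance <- stage("concordance",
                             concordance(res$assignments, md))
    res$composition <- species_composition(res$assignments, md)
    summary$concordance_r2 <- res$concordance$effect_r2
    summary$concordance_p <- res$concordance$p
    say("concordance: Cramer's V2 = %.3f", summary$concordance_r2)
  }

  res$metadata <- md
  res$genotypes <- g
  res$summary <- summary
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg)
  invisible(res)
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  flat <- cfg[!vapply(cfg, is.list, logical(1))]
  manifest <- c(
    vapply(names(flat), function(k) paste0(k, ": ", paste(format(flat[[k]]),
                                                          collapse = ",")), ""),
    if (!is.null(cfg$sim)) {
      vapply(names(unclass(cfg$sim)), function(k) {
        paste0("sim.", k, ": ", paste(format(cfg$sim[[k]]), collapse = ","))
      }, "")
    })
  writeLines(manifest, p("manifest.txt"))
  write_metadata(res$metadata, p("metadata.tsv"))
  if (!is.null(res$assignments)) {
    readr::write_tsv(res$assignments, p("assignments.tsv"), progress = FALSE)
  }
  if (!is.null(res$fst)) write_matrix_tsv(res$fst, p("fst_matrix.tsv"))
  if (!is.null(res$pi)) readr::write_tsv(res$pi, p("pi_windows.tsv"), progress = FALSE)
  if (!is.null(res$dist)) write_matrix_tsv(res$dist, p("distance_matrix.tsv"))
  if (!is.null(res$tree)) ape::write.tree(res$tree, p("nj_tree.nwk"))
  if (!is.null(res$ld)) readr::write_tsv(res$ld, p("ld_decay.tsv"), progress = FALSE)
  if (!is.null(res$mantel)) {
    readr::write_tsv(glance(res$mantel), p("mantel.tsv"), progress = FALSE)
  }
  if (!is.null(res$cpnet)) {
    write_network(res$cpnet$network, p("cp_network_edges.tsv"), p("cp_network.gml"))
    readr::write_tsv(res$cpnet$assignments, p("cp_groups.tsv"), progress = FALSE)
    readr::write_tsv(res$cpnet$polarity, p("cp_polarity.tsv"), progress = FALSE)
  }
  if (!is.null(res$domestication)) {
    readr::write_tsv(res$domestication$selected, p("rc_selected_snps.tsv"),
                     progress = FALSE)
    eh <- res$domestication$haplotypes
    eh$focal <- vapply(eh$focal, function(f) paste(names(f), f, sep = "=",
                                                   collapse = ";"), "")
    readr::write_tsv(eh, p("rc_extended_haplotypes.tsv"), progress = FALSE)
  }
  if (!is.null(res$concordance)) {
    readr::write_tsv(tidy(res$concordance), p("concordance_table.tsv"),
                     progress = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(res)
}

#' Write a labeled symmetric matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(label = rownames(m)), tibble::as_tibble(m)),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x$label
  m
}
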