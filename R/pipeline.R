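#' Pipeline configuration
#'
#' All numeric thresholds of the classification pipeline in one place.
#' Defaults: permissive profile inclusion E-values (1.0 for the omp85-type
#' profile, 0.1 for the tpsb-type) with a larger reporting threshold (10)
#' that also retains below-inclusion hits; all-vs-all edge cutoff 1e-2 for
#' Markov clustering with inflation 1.5 (curation pass) and 1.3 (final
#' pass); 250-aa minimum length; 0.80 identity reduction and 1e-5 cutoff for
#' sequence-region networks; 0.50 reduction and 1e-3 cutoff for the POTRA
#' network; 20-aa minimum N-terminus; 25-125 aa POTRA retention band;
#' lipobox cysteine window 15-40.
#'
#' @param sequences,seed_omp85,seed_tpsb,seed_potra,annotations,taxa,truth
#'   Input file paths (FASTA / aligned FASTA / TSV); may be omitted when the
#'   pipeline is run on an in-memory dataset.
#' @param outdir Output directory (NULL: nothing written).
#' @param incE_omp85,incE_tpsb Inclusion E-value thresholds per profile.
#' @param report_evalue Reporting threshold; hits up to this E-value enter
#'   the dataset ("include all hits below the inclusion cutoff").
#' @param mcl_edge_cutoff E-value cutoff for graph edges.
#' @param inflation_curation,inflation_final MCL inflation per pass.
#' @param min_length Minimum sequence length after curation.
#' @param reduction_sequences,reduction_potra Greedy-reduction identities.
#' @param cutoff_networks,cutoff_potra_net Network edge E-value cutoffs.
#' @param min_nterm Minimum reported N-terminus length.
#' @param potra_min_len,potra_max_len POTRA segment retention band.
#' @param potra_scan_evalue Per-sequence E-value bound for POTRA scanning.
#' @param lipobox_window_start,lipobox_window_end Lipobox cysteine window.
#' @param pseudocount_weight Profile pseudocount mass.
#' @param calibration_n,calibration_length Profile calibration settings.
#' @param seed Master seed for every stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sequences = NULL, seed_omp85 = NULL,
                            seed_tpsb = NULL, seed_potra = NULL,
                            annotations = NULL, taxa = NULL, truth = NULL,
                            outdir = NULL,
                            incE_omp85 = 1.0, incE_tpsb = 0.1,
                            report_evalue = 10,
                            mcl_edge_cutoff = 1e-2,
                            inflation_curation = 1.5, inflation_final = 1.3,
                            min_length = 250,
                            reduction_sequences = 0.80,
                            reduction_potra = 0.50,
                            cutoff_networks = 1e-5, cutoff_potra_net = 1e-3,
                            min_nterm = 20,
                            potra_min_len = 25, potra_max_len = 125,
                            potra_scan_evalue = 1e-3,
                            lipobox_window_start = 15,
                            lipobox_window_end = 40,
                            pseudocount_weight = 5,
                            calibration_n = 300, calibration_length = 350,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(incE_omp85 > 0, incE_tpsb > 0, report_evalue > 0,
            mcl_edge_cutoff > 0, inflation_curation > 1, inflation_final > 1,
            min_length >= 1, reduction_sequences > 0, reduction_potra > 0,
            cutoff_networks > 0, cutoff_potra_net > 0, min_nterm >= 1,
            potra_min_len >= 1, potra_max_len >= potra_min_len)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

stage_report <- function(reports, stage, n_in, n_out, t0, note = "") {
  reports[[length(reports) + 1L]] <-
    data.frame(stage = stage, n_in = n_in, n_out = n_out,
               elapsed = round(as.numeric(Sys.time()) - t0, 2),
               note = note, stringsAsFactors = FALSE)
  reports
}

# Representative-level annotation: contaminant label wins over omp85_like,
# which wins over unknown, mirroring removal of whole 100%-identity groups
# judged as contaminants.
group_annotation <- function(groups, annotations) {
  lab <- stats::setNames(annotations$label, annotations$id)
  rows <- lapply(names(groups), function(rep) {
    labels <- lab[groups[[rep]]]
    labels <- labels[!is.na(labels)]
    contam <- labels[startsWith(labels, "contaminant")]
    pick <- if (length(contam) > 0) contam[1]
    else if (any(labels == "omp85_like")) "omp85_like"
    else "unknown"
    data.frame(id = rep, label = pick, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full classification pipeline
#'
#' Stage order: search both barrel profiles (reporting threshold), merge by
#' higher score, collapse identical sequences, all-vs-all + Markov clustering
#' (curation inflation), propagate contaminant/superfamily labels over
#' clusters, drop contaminant clusters, apply the length filter, re-cluster
#' the curated set (final inflation), partition sequences into barrel and
#' N-terminal regions from hit envelopes, scan and consolidate POTRA repeats
#' per cluster, detect lipoprotein signals, build full-length / barrel /
#' N-terminus / POTRA similarity networks, and compute taxonomic distribution
#' matrices.  Deterministic given configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param data Optional in-memory dataset as returned by
#'   [generate_dataset()]; when NULL, inputs are read from the config paths.
#' @return List of class `pipeline_result` (see elements in the examples and
#'   vignette), including `final_clusters`, `curation`, `partition`,
#'   `potras`, `lipobox`, `networks`, `presence`, `copies`, `reports`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  reports <- list()
  t0 <- as.numeric(Sys.time())

  if (is.null(data)) {
    records <- read_fasta(config$sequences)
    seeds <- list(omp85 = read_fasta(config$seed_omp85),
                  tpsb = read_fasta(config$seed_tpsb),
                  potra = read_fasta(config$seed_potra))
    annotations <- utils::read.delim(config$annotations,
                                     stringsAsFactors = FALSE,
                                     colClasses = "character")
    taxa <- read_taxa(config$taxa)
    truth <- if (!is.null(config$truth))
      utils::read.delim(config$truth, stringsAsFactors = FALSE,
                        colClasses = "character") else NULL
  } else {
    records <- data$records
    seeds <- lapply(data$seeds, function(s)
      data.frame(id = names(s), residues = unname(s),
                 stringsAsFactors = FALSE))
    annotations <- data$annotations
    taxa <- data$taxa
    truth <- data$truth
  }
  if (nrow(records) == 0L) stop("stage search: empty input sequence set")
  records$taxon_id <- NULL   # taxon links come from the tables
  if (!is.null(truth)) {
    records$taxon_id <- truth$taxon_id[match(records$id, truth$id)]
    records$taxon_id[is.na(records$taxon_id)] <- ""
  } else {
    records$taxon_id <- ""
  }
  params <- alignment_params()

  # -- profiles -------------------------------------------------------------
  prof_omp <- build_profile(seeds$omp85, config$pseudocount_weight, "omp85")
  prof_tps <- build_profile(seeds$tpsb, config$pseudocount_weight, "tpsb")
  prof_pot <- build_profile(seeds$potra, config$pseudocount_weight, "potra")
  prof_omp <- calibrate(prof_omp, config$calibration_n,
                        config$calibration_length,
                        derive_seed(config$seed, "cal_omp85"))
  prof_tps <- calibrate(prof_tps, config$calibration_n,
                        config$calibration_length,
                        derive_seed(config$seed, "cal_tpsb"))
  prof_pot <- calibrate(prof_pot, config$calibration_n,
                        config$calibration_length,
                        derive_seed(config$seed, "cal_potra"))

  # -- search & merge -------------------------------------------------------
  hits_omp <- profile_search(prof_omp, records, config$report_evalue)
  hits_tps <- profile_search(prof_tps, records, config$report_evalue)
  hits_omp$included <- hits_omp$evalue <= config$incE_omp85
  hits_tps$included <- hits_tps$evalue <= config$incE_tpsb
  merged <- merge_hits(hits_omp, hits_tps)
  retrieved <- records[records$id %in% merged$target_id, , drop = FALSE]
  reports <- stage_report(reports, "search", nrow(records), nrow(retrieved),
                          t0)
  if (nrow(retrieved) < 2L) stop("stage search: fewer than 2 hits retrieved")

  # -- duplicate collapse ---------------------------------------------------
  col <- collapse_identical(retrieved)
  reps <- col$representatives
  reports <- stage_report(reports, "collapse", nrow(retrieved), nrow(reps),
                          t0)

  # -- curation clustering + label propagation ------------------------------
  hits1 <- all_vs_all(reps, params, evalue_cutoff = config$mcl_edge_cutoff,
                      stats = "score_only")
  g1 <- build_graph(hits1, config$mcl_edge_cutoff, nodes = sort(reps$id))
  clus1 <- mcl(g1, mcl_options(inflation = config$inflation_curation))
  rep_ann <- group_annotation(col$groups, annotations)
  cur <- propagate_labels(clus1, rep_ann)
  kept_reps <- reps[reps$id %in% cur$kept_ids, , drop = FALSE]
  reports <- stage_report(reports, "curation", nrow(reps), nrow(kept_reps),
                          t0)

  # -- length filter --------------------------------------------------------
  fl <- filter_length(kept_reps, config$min_length)
  kept_reps <- fl$kept
  reports <- stage_report(reports, "length_filter",
                          nrow(fl$kept) + nrow(fl$removed), nrow(kept_reps),
                          t0)

  # -- final clustering -----------------------------------------------------
  hits2 <- all_vs_all(kept_reps, params,
                      evalue_cutoff = config$mcl_edge_cutoff,
                      stats = "score_only")
  g2 <- build_graph(hits2, config$mcl_edge_cutoff,
                    nodes = sort(kept_reps$id))
  clus2 <- mcl(g2, mcl_options(inflation = config$inflation_final))
  reports <- stage_report(reports, "final_mcl", nrow(kept_reps),
                          length(clus2$clusters), t0)

  # cluster -> subfamily labels by majority truth/annotation vote
  labels <- label_clusters(clus2, truth, annotations)

  # expand representatives back to their duplicate-group members
  members_of <- function(ids) unlist(col$groups[ids], use.names = FALSE)
  final_members <- members_of(kept_reps$id)

  # -- domain partitioning --------------------------------------------------
  part <- split_domains(kept_reps, merged[merged$target_id %in% kept_reps$id,
                                          , drop = FALSE], config$min_nterm)
  barrel <- region_records(kept_reps, part, "barrel")
  nterm <- region_records(kept_reps, part, "nterm")
  reports <- stage_report(reports, "partition", nrow(kept_reps),
                          nrow(part), t0,
                          note = paste0(nrow(nterm), " with N-terminus"))

  # -- POTRA scan + per-cluster consensus -----------------------------------
  assign2 <- cluster_assignment(clus2)
  pot_raw <- lapply(seq_len(nrow(nterm)), function(i) {
    scan_potras(nterm$residues[i], prof_pot, config$potra_min_len,
                config$potra_max_len, config$potra_scan_evalue,
                id = nterm$id[i])
  })
  pot_raw <- do.call(rbind, pot_raw)
  potras <- if (!is.null(pot_raw) && nrow(pot_raw) > 0) {
    pot_raw$cluster <- assign2[pot_raw$id]
    done <- lapply(split(pot_raw, pot_raw$cluster), consensus_potra_set)
    out <- do.call(rbind, done)
    rownames(out) <- NULL
    out
  } else {
    data.frame(id = character(0), index = character(0), start = integer(0),
               end = integer(0), score = numeric(0), cluster = integer(0))
  }
  reports <- stage_report(reports, "potra_scan", nrow(nterm),
                          nrow(potras), t0)

  # -- lipoprotein signals --------------------------------------------------
  lipo <- do.call(rbind, lapply(seq_len(nrow(kept_reps)), function(i) {
    detect_lipobox(kept_reps$residues[i], config$lipobox_window_start,
                   config$lipobox_window_end, id = kept_reps$id[i])
  }))
  reports <- stage_report(reports, "lipobox", nrow(kept_reps),
                          sum(lipo$positive), t0)

  # -- similarity networks --------------------------------------------------
  attr_tab <- data.frame(
    id = kept_reps$id,
    subfamily = labels[as.character(assign2[kept_reps$id])],
    phylum = taxa$phylum[match(kept_reps$taxon_id, taxa$taxon_id)],
    stringsAsFactors = FALSE)
  red_full <- greedy_centroid(kept_reps, config$reduction_sequences, params)
  cent_ids <- red_full$centroids
  net_full <- build_network(kept_reps[match(cent_ids, kept_reps$id), ,
                                      drop = FALSE],
                            identity_reduction = NULL,
                            evalue_cutoff = config$cutoff_networks,
                            attributes = attr_tab, params = params)
  net_barrel <- build_network(barrel[barrel$id %in% cent_ids, , drop = FALSE],
                              identity_reduction = NULL,
                              evalue_cutoff = config$cutoff_networks,
                              attributes = attr_tab, params = params)
  net_nterm <- build_network(nterm[nterm$id %in% cent_ids, , drop = FALSE],
                             identity_reduction = NULL,
                             evalue_cutoff = config$cutoff_networks,
                             attributes = attr_tab, params = params)
  net_potra <- if (nrow(potras) > 0) {
    seg_recs <- data.frame(
      id = paste0(potras$id, "/", potras$index),
      residues = substr(nterm$residues[match(potras$id, nterm$id)],
                        potras$start, potras$end),
      taxon_id = "", description = "potra segment",
      stringsAsFactors = FALSE)
    seg_attr <- data.frame(
      id = seg_recs$id,
      subfamily = attr_tab$subfamily[match(potras$id, attr_tab$id)],
      phylum = attr_tab$phylum[match(potras$id, attr_tab$id)],
      potra_index = potras$index, stringsAsFactors = FALSE)
    build_network(seg_recs, identity_reduction = config$reduction_potra,
                  evalue_cutoff = config$cutoff_potra_net,
                  attributes = seg_attr, params = params)
  } else NULL
  reports <- stage_report(reports, "networks", nrow(kept_reps),
                          length(cent_ids), t0)

  # -- taxonomic distribution ----------------------------------------------
  # expand to duplicate-group members so per-genome copy numbers are real
  assignments <- do.call(rbind, lapply(kept_reps$id, function(rep) {
    mem <- col$groups[[rep]]
    data.frame(id = mem,
               subfamily = attr_tab$subfamily[attr_tab$id == rep],
               taxon_id = if (!is.null(truth))
                 truth$taxon_id[match(mem, truth$id)] else "",
               stringsAsFactors = FALSE)
  }))
  presence <- presence_matrix(assignments, taxa)
  copies <- copy_numbers(assignments, taxa)
  reports <- stage_report(reports, "distribution", nrow(assignments),
                          length(labels), t0)

  result <- structure(list(
    config = config, profiles = list(omp85 = prof_omp, tpsb = prof_tps,
                                     potra = prof_pot),
    hits = list(omp85 = hits_omp, tpsb = hits_tps, merged = merged),
    groups = col$groups,
    curation_clusters = clus1, curation = cur,
    kept_records = kept_reps, final_members = final_members,
    final_clusters = clus2, cluster_labels = labels,
    partition = part, barrel_records = barrel, nterm_records = nterm,
    potras = potras, lipobox = lipo,
    networks = list(full = net_full, barrel = net_barrel,
                    nterm = net_nterm, potra = net_potra),
    assignments = assignments, presence = presence, copies = copies,
    reports = do.call(rbind, reports)), class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

# Majority truth/annotation vote per final cluster; falls back to cluster_k.
label_clusters <- function(clustering, truth, annotations) {
  n <- length(clustering$clusters)
  labels <- paste0("cluster_", seq_len(n))
  src <- NULL
  if (!is.null(truth)) {
    src <- stats::setNames(truth$template_name, truth$id)
  } else if (!is.null(annotations)) {
    keep <- annotations$label != "unknown"
    src <- stats::setNames(annotations$label[keep], annotations$id[keep])
  }
  if (!is.null(src)) {
    for (k in seq_len(n)) {
      v <- src[clustering$clusters[[k]]]
      v <- v[!is.na(v)]
      if (length(v) > 0) {
        tab <- sort(table(v), decreasing = TRUE)
        labels[k] <- paste0(names(tab)[1], "_c", k)
      }
    }
  }
  stats::setNames(labels, as.character(seq_len(n)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  print(x$reports, row.names = FALSE)
  cat("final clusters: ", length(x$final_clusters$clusters), "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_profile_hits(result$hits$merged[, c("query_profile", "target_id",
                                            "score", "evalue", "env_start",
                                            "env_end")], p("hits_merged.tsv"))
  write_clustering(result$curation_clusters, p("clusters_curation.tsv"))
  write_curation(result$curation, result$curation_clusters, p("curation.tsv"))
  tab <- clustering_table(result$final_clusters)
  tab$subfamily <- result$cluster_labels[as.character(tab$cluster_id)]
  utils::write.table(tab, p("clusters_final.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$partition, p("partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$potras, p("potras.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$lipobox, p("lipobox.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(result$barrel_records, p("barrel.fasta"))
  write_fasta(result$nterm_records, p("nterm.fasta"))
  for (nm in names(result$networks)) {
    if (is.null(result$networks[[nm]])) next
    write_network(result$networks[[nm]], p(paste0("network_", nm,
                                                  "_edges.tsv")),
                  p(paste0("network_", nm, "_nodes.tsv")))
  }
  pm <- data.frame(phylum = rownames(result$presence), result$presence,
                   check.names = FALSE)
  utils::write.table(pm, p("presence_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cn <- data.frame(taxon_id = rownames(result$copies), result$copies,
                   check.names = FALSE)
  utils::write.table(cn, p("copy_numbers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$reports, p("stage_reports.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
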