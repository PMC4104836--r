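#' Build an attributed similarity network over a region sequence set
#'
#' Diversity is first reduced by greedy centroid clustering at
#' `identity_reduction`; the network nodes are the centroids and edges come
#' from an all-vs-all alignment of the centroids at the E-value cutoff, with
#' self-loops removed.  Edge weight is `-log10(E)` (capped).
#'
#' @param region_records Sequence data frame (full-length, barrel, N-terminus
#'   or POTRA sequences).
#' @param identity_reduction Greedy-reduction identity threshold (default
#'   0.80; the POTRA path reduces at 0.50 upstream).  NULL skips the
#'   reduction and uses the records as network nodes directly (used when the
#'   centroid set was computed upstream, e.g. shared across regions).
#' @param evalue_cutoff Edge cutoff (defaults: 1e-5 for sequence regions,
#'   1e-3 for POTRA networks).
#' @param attributes Optional data frame of node attributes (`id` plus e.g.
#'   `subfamily`, `phylum`, `region`, `potra_index`); missing values become
#'   "unknown".
#' @param params [alignment_params()] for both stages.
#' @return Object of class `attributed_network`: `graph`
#'   (`similarity_graph` over centroid ids), `nodes` (attribute data frame),
#'   `reduction` (the greedy clustering result).
#' @export
build_network <- function(region_records, identity_reduction = 0.80,
                          evalue_cutoff = 1e-5, attributes = NULL,
                          params = alignment_params()) {
  if (is.null(identity_reduction)) {      # reduction done upstream
    red <- list(clustering = NULL, centroids = region_records$id)
  } else {
    red <- greedy_centroid(region_records, identity_reduction, params)
  }
  cent <- region_records[match(red$centroids, region_records$id), ,
                         drop = FALSE]
  hits <- if (nrow(cent) >= 2L) {
    all_vs_all(cent, params, evalue_cutoff = evalue_cutoff,
               include_self = FALSE, stats = "score_only")
  } else {
    data.frame(id_a = character(0), id_b = character(0),
               evalue = numeric(0))
  }
  graph <- build_graph(hits, evalue_cutoff = evalue_cutoff,
                       nodes = sort(cent$id))
  nodes <- data.frame(id = graph$nodes, stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    extra <- attributes[match(nodes$id, attributes$id), , drop = FALSE]
    for (col in setdiff(names(extra), "id")) {
      v <- extra[[col]]
      v[is.na(v)] <- "unknown"
      nodes[[col]] <- v
    }
  }
  structure(list(graph = graph, nodes = nodes, reduction = red),
            class = "attributed_network")
}

#' Connected components of a network
#'
#' @param network An `attributed_network` (or `similarity_graph`).
#' @return List of character vectors of node ids, each sorted, ordered by
#'   their smallest node id.
#' @export
network_components <- function(network) {
  graph <- if (inherits(network, "attributed_network")) network$graph else
    network
  n <- length(graph$nodes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  }
  memb <- igraph::components(g)$membership
  comps <- lapply(split(seq_len(n), memb), function(ix) sort(graph$nodes[ix]))
  names(comps) <- NULL
  comps[order(vapply(comps, min, character(1)))]
}

#' Presence/absence distribution matrix over phyla
#'
#' For each phylum and subfamily, the percentage of complete-proteome genomes
#' of that phylum containing at least one member.  Taxa not flagged as
#' complete proteomes are excluded entirely; a phylum without complete
#' genomes yields NA cells (missing, not 0).
#'
#' @param assignments Data frame: `id`, `subfamily`, `taxon_id`.
#' @param taxa Taxon table ([read_taxa()] format).
#' @return Numeric matrix, phyla x subfamilies, values in `[0, 100]` or NA.
#' @export
presence_matrix <- function(assignments, taxa) {
  stopifnot(all(c("id", "subfamily", "taxon_id") %in% names(assignments)))
  phyla <- sort(unique(taxa$phylum))
  fams <- sort(unique(assignments$subfamily))
  complete <- taxa[taxa$complete_proteome, , drop = FALSE]
  a <- assignments[assignments$taxon_id %in% complete$taxon_id, , drop = FALSE]
  a$phylum <- complete$phylum[match(a$taxon_id, complete$taxon_id)]
  m <- matrix(NA_real_, length(phyla), length(fams),
              dimnames = list(phyla, fams))
  for (p in phyla) {
    genomes <- complete$taxon_id[complete$phylum == p]
    if (length(genomes) == 0L) next
    for (f in fams) {
      with_f <- unique(a$taxon_id[a$phylum == p & a$subfamily == f])
      m[p, f] <- 100 * length(with_f) / length(genomes)
    }
  }
  m
}

#' Per-genome copy-number table
#'
#' Plain counts of members per (taxon, subfamily) over complete proteomes
#' only.
#'
#' @inheritParams presence_matrix
#' @return Integer matrix, complete-proteome taxa x subfamilies.
#' @export
copy_numbers <- function(assignments, taxa) {
  complete <- taxa[taxa$complete_proteome, , drop = FALSE]
  fams <- sort(unique(assignments$subfamily))
  a <- assignments[assignments$taxon_id %in% complete$taxon_id, , drop = FALSE]
  m <- matrix(0L, nrow(complete), length(fams),
              dimnames = list(complete$taxon_id, fams))
  if (nrow(a) > 0) {
    tab <- table(factor(a$taxon_id, levels = complete$taxon_id),
                 factor(a$subfamily, levels = fams))
    m[] <- as.integer(tab)
  }
  m
}

#' Write a network as edge-list and node-attribute TSVs
#'
#' @param network An `attributed_network`.
#' @param edge_path,node_path Output paths.
#' @return Invisibly, `edge_path`.
#' @export
write_network <- function(network, edge_path, node_path) {
  e <- network$graph$edges
  out <- data.frame(source = network$graph$nodes[e$i],
                    target = network$graph$nodes[e$j],
                    weight = round(e$weight, 4))
  utils::write.table(out, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}

#' Plot a presence/absence heatmap
#'
#' Simple image-based heatmap of a [presence_matrix()], white (0%) to deep
#' blue (100%); NA cells are left blank.
#'
#' @param m Matrix from [presence_matrix()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `m`.
#' @export
plot_presence_matrix <- function(m, ...) {
  pal <- grDevices::colorRampPalette(c("white", "darkblue"))(100)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ,
                                                          drop = FALSE]),
                  col = pal, zlim = c(0, 100), axes = FALSE, xlab = "",
                  ylab = "", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.8)
  invisible(m)
}
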