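#' Build a similarity graph from pair hits
#'
#' Edges connect pairs with `evalue <= evalue_cutoff`; the default weight rule
#' is `min(cap, -log10(max(E, 1e-200)))` with `cap = 200`.  Self pairs are
#' dropped.  Nodes absent from any hit stay in the graph as isolated nodes
#' when listed in `nodes`.
#'
#' @param pair_hits Data frame with columns `id_a`, `id_b`, `evalue`.
#' @param evalue_cutoff Drop hits above this E-value (default 1e-2).
#' @param weight_rule Function E-value -> weight, or NULL for the default.
#' @param nodes Optional character vector of all node ids (defaults to the
#'   ids present in the kept hits).
#' @param cap Weight cap for the default rule.
#' @return Object of class `similarity_graph`: `nodes` (ordered ids) and
#'   `edges` (data frame `i`, `j`, `weight` with `i < j` by node order).
#' @export
build_graph <- function(pair_hits, evalue_cutoff = 1e-2, weight_rule = NULL,
                        nodes = NULL, cap = 200) {
  if (is.null(weight_rule)) {
    weight_rule <- function(e) pmin(cap, -log10(pmax(e, 1e-200)))
  }
  h <- pair_hits[pair_hits$evalue <= evalue_cutoff &
                   pair_hits$id_a != pair_hits$id_b, , drop = FALSE]
  if (is.null(nodes)) nodes <- sort(unique(c(h$id_a, h$id_b)))
  i <- match(h$id_a, nodes)
  j <- match(h$id_b, nodes)
  if (anyNA(i) || anyNA(j)) stop("hit references id missing from nodes")
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  w <- weight_rule(h$evalue)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {            # keep the best (largest) weight
    ord <- order(key, -w)
    keep <- !duplicated(key[ord])
    lo <- lo[ord][keep]; hi <- hi[ord][keep]; w <- w[ord][keep]
  }
  stopifnot(all(is.finite(w)), all(w >= 0))
  edges <- data.frame(i = lo, j = hi, weight = w)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Markov clustering options
#'
#' @param inflation Entrywise-power parameter (> 1); granularity knob.
#' @param expansion Matrix-power parameter (integer >= 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @param convergence_tol Stop when the largest entry change falls below this.
#' @param selfloop_weight Self-loop weight added to every node before
#'   normalization.
#' @return List of class `mcl_options`.
#' @export
mcl_options <- function(inflation = 1.5, expansion = 2L,
                        prune_threshold = 1e-5, max_iter = 100L,
                        convergence_tol = 1e-9, selfloop_weight = 1.0) {
  stopifnot(inflation > 1, expansion >= 2)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 selfloop_weight = selfloop_weight), class = "mcl_options")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Native implementation of the MCL iteration: add self-loops, column-
#' normalize to a stochastic matrix, then alternate expansion (matrix power),
#' inflation (entrywise power + column renormalization) and pruning until the
#' largest entry change drops below the tolerance or the iteration cap is
#' reached.  In the limit matrix, attractors are nodes with positive diagonal;
#' each attractor row's support is a cluster; a node claimed by several
#' clusters goes to the one whose first attractor has the smallest node index,
#' making the output a deterministic partition.  Isolated nodes become
#' singletons.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param options An [mcl_options()] object.
#' @return Object of class `clustering`: `clusters` (list of character id
#'   vectors, ordered by smallest member node index), plus `converged` and
#'   `iterations`.
#' @export
mcl <- function(graph, options = mcl_options()) {
  stopifnot(inherits(graph, "similarity_graph"))
  n <- length(graph$nodes)
  if (n == 0L) stop("empty graph")
  M <- matrix(0, n, n)
  e <- graph$edges
  if (nrow(e) > 0) {
    M[cbind(e$i, e$j)] <- e$weight
    M[cbind(e$j, e$i)] <- e$weight
  }
  diag(M) <- diag(M) + options$selfloop_weight
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  it <- 0L
  while (it < options$max_iter) {
    it <- it + 1L
    prev <- M
    P <- M
    for (k in seq_len(options$expansion - 1L)) P <- P %*% M
    P <- P ^ options$inflation
    P <- sweep(P, 2, colSums(P), "/")
    P[P < options$prune_threshold] <- 0
    cs <- colSums(P)
    zero <- cs == 0          # a fully pruned column keeps its diagonal
    if (any(zero)) {
      P[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    P <- sweep(P, 2, cs, "/")
    M <- P
    if (max(abs(M - prev)) < options$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", options$max_iter,
            " iterations; interpreting current matrix")
  }
  interpret_mcl_matrix(M, graph$nodes, converged, it)
}

# Attractor-based interpretation of an (approximately) idempotent MCL matrix.
interpret_mcl_matrix <- function(M, nodes, converged, iterations) {
  n <- length(nodes)
  attractors <- which(diag(M) > 0)
  assign <- rep(NA_integer_, n)
  # Group attractors into attractor systems: attractors whose rows overlap on
  # some column belong to the same cluster.  Build clusters from attractor
  # rows; a non-attractor claimed by several clusters goes to the cluster
  # whose smallest attractor index is least.
  support <- lapply(attractors, function(a) which(M[a, ] > 0))
  cluster_of_attr <- seq_along(attractors)
  if (length(attractors) > 1) {
    for (x in seq_along(attractors)) {
      for (y in seq_len(x - 1L)) {
        if (length(intersect(support[[x]], support[[y]])) > 0 ||
            attractors[y] %in% support[[x]] || attractors[x] %in% support[[y]]) {
          old <- cluster_of_attr[x]
          new <- cluster_of_attr[y]
          cluster_of_attr[cluster_of_attr == old] <- new
        }
      }
    }
  }
  for (cid in unique(cluster_of_attr)) {
    attrs <- attractors[cluster_of_attr == cid]
    memb <- sort(unique(c(attrs, unlist(support[cluster_of_attr == cid]))))
    key <- min(attrs)
    for (m in memb) {
      if (is.na(assign[m])) {
        assign[m] <- key
      } else {
        assign[m] <- min(assign[m], key)   # smallest attractor index wins
      }
    }
  }
  assign[is.na(assign)] <- which(is.na(assign))  # isolated -> singleton
  ids <- split(seq_len(n), assign)
  ord <- order(vapply(ids, min, integer(1)))
  clusters <- lapply(ids[ord], function(ix) nodes[ix])
  names(clusters) <- NULL
  structure(list(clusters = clusters, converged = converged,
                 iterations = iterations), class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("clustering: ", length(x$clusters), " clusters over ", sum(sizes),
      " ids (sizes ", paste(utils::head(sort(sizes, decreasing = TRUE), 10),
                            collapse = ", "),
      if (length(sizes) > 10) ", ...", ")\n", sep = "")
  invisible(x)
}

#' Cluster membership as a data frame
#' @param clustering A `clustering` object.
#' @return Data frame with columns `cluster_id` (1-based), `member_id`.
#' @export
clustering_table <- function(clustering) {
  data.frame(
    cluster_id = rep(seq_along(clustering$clusters),
                     lengths(clustering$clusters)),
    member_id = unlist(clustering$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# cluster id (index into clusters) for each id, named vector
cluster_assignment <- function(clustering) {
  tab <- clustering_table(clustering)
  stats::setNames(tab$cluster_id, tab$member_id)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in order of decreasing length (ties by id order);
#' each sequence joins the first existing centroid to which its local-
#' alignment identity is at or above the threshold, otherwise it seeds a new
#' cluster.  Mirrors fast centroid-based reduction tools; deterministic.
#'
#' @param records Sequence data frame.
#' @param identity_threshold Identity threshold in (0, 1].
#' @param params An [alignment_params()] object used for the alignments.
#' @return List with `clustering` (a `clustering` object, clusters in
#'   centroid-creation order) and `centroids` (centroid ids in creation
#'   order).
#' @export
greedy_centroid <- function(records, identity_threshold,
                            params = alignment_params()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            is.data.frame(records), nrow(records) >= 1L)
  ord <- order(-nchar(records$residues), records$id)
  recs <- records[ord, , drop = FALSE]
  codes <- lapply(recs$residues, encode_residues)
  centroids <- integer(0)              # row indices into recs
  members <- list()
  for (i in seq_len(nrow(recs))) {
    hit <- 0L
    if (length(centroids) > 0) {
      hit <- cpp_greedy_first_match(codes[[i]], codes[centroids],
                                    params$matrix, params$gap_open,
                                    params$gap_extend, identity_threshold)
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      members[[length(centroids)]] <- i
    } else {
      members[[hit]] <- c(members[[hit]], i)
    }
  }
  clusters <- lapply(members, function(ix) recs$id[ix])
  list(clustering = structure(list(clusters = clusters, converged = TRUE,
                                   iterations = 0L), class = "clustering"),
       centroids = recs$id[centroids])
}

#' Write a clustering as TSV
#' @param clustering A `clustering` object.
#' @param path Output path.
#' @param centroids Optional centroid/attractor ids flagged in the output.
#' @return Invisibly, `path`.
#' @export
write_clustering <- function(clustering, path, centroids = NULL) {
  tab <- clustering_table(clustering)
  tab$is_centroid <- as.integer(tab$member_id %in% centroids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
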