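#' Propagate confident labels over clusters
#'
#' Cluster-level contaminant curation: a cluster containing at least one
#' contaminant label and no superfamily label is discarded entirely
#' (unknowns included); a cluster containing at least one superfamily label
#' and no contaminant is kept entirely; a cluster with both is flagged
#' ambiguous, its members discarded, and a warning emitted; a cluster of only
#' unknowns is kept (its members were retrieved by the profile search).
#'
#' @param clustering A `clustering` object.
#' @param annotations Data frame with columns `id`, `label`; labels are
#'   `omp85_like`, `contaminant:<family>`, or `unknown`.  Clustered ids
#'   missing from the table are treated as unknown (and reported).
#' @return List of class `curation_result`: `kept_ids`, `discarded_ids`
#'   (disjoint, union = all clustered ids), `cluster_status` (character
#'   vector, one of kept/discarded/ambiguous per cluster), and
#'   `missing_ids` (ids that had no annotation row).
#' @export
propagate_labels <- function(clustering, annotations) {
  stopifnot(inherits(clustering, "clustering"), is.data.frame(annotations),
            all(c("id", "label") %in% names(annotations)))
  lab <- stats::setNames(annotations$label, annotations$id)
  all_ids <- unlist(clustering$clusters, use.names = FALSE)
  missing <- setdiff(all_ids, names(lab))
  if (length(missing) > 0) {
    message(length(missing), " clustered id(s) missing from annotations; ",
            "treated as unknown")
  }
  status <- character(length(clustering$clusters))
  kept <- character(0)
  discarded <- character(0)
  for (k in seq_along(clustering$clusters)) {
    ids <- clustering$clusters[[k]]
    labels <- ifelse(ids %in% names(lab), lab[ids], "unknown")
    has_contam <- any(startsWith(labels, "contaminant"))
    has_member <- any(labels == "omp85_like")
    if (has_contam && has_member) {
      status[k] <- "ambiguous"
      discarded <- c(discarded, ids)
      warning("cluster ", k, " mixes contaminant and superfamily labels; ",
              "discarding its ", length(ids), " member(s)")
    } else if (has_contam) {
      status[k] <- "discarded"
      discarded <- c(discarded, ids)
    } else {
      status[k] <- "kept"          # superfamily labels or unknowns only
      kept <- c(kept, ids)
    }
  }
  structure(list(kept_ids = kept, discarded_ids = discarded,
                 cluster_status = status, missing_ids = missing),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("curation: ", length(x$kept_ids), " kept, ", length(x$discarded_ids),
      " discarded (", sum(x$cluster_status == "discarded"), " contaminant + ",
      sum(x$cluster_status == "ambiguous"), " ambiguous clusters)\n", sep = "")
  invisible(x)
}

#' Minimum-length filter
#'
#' Removes sequences shorter than `min_length` residues; the boundary is
#' strict ("less than"), so a sequence of exactly `min_length` is kept.
#'
#' @param records Sequence data frame.
#' @param min_length Minimum length in residues (default 250).
#' @return List with `kept` and `removed` sequence data frames.
#' @export
filter_length <- function(records, min_length = 250) {
  stopifnot(min_length >= 1)
  keep <- nchar(records$residues) >= min_length
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Write a curation result as TSV
#' @param curation A `curation_result`.
#' @param clustering The clustering it was computed on.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curation <- function(curation, clustering, path) {
  tab <- clustering_table(clustering)
  tab$status <- ifelse(tab$member_id %in% curation$kept_ids, "kept",
                       "discarded")
  tab$reason <- curation$cluster_status[tab$cluster_id]
  utils::write.table(tab[, c("member_id", "status", "cluster_id", "reason")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
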