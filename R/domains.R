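#' Partition a sequence into barrel and N-terminal regions
#'
#' The barrel runs from the best profile hit's envelope start to the end of
#' the sequence; everything before it is the N-terminal region, reported only
#' when at least `min_nterm` residues long (default 20, strict "less than"
#' removal).  Sequences with a short N-terminus stay in barrel analyses.
#'
#' @param records Sequence data frame.
#' @param hits Merged profile hits ([merge_hits()]) with one row per target.
#' @param min_nterm Minimum N-terminus length to report.
#' @return Data frame: `id`, `barrel_start`, `barrel_end`, `nterm_start`,
#'   `nterm_end` (NA when absent), `source_profile`.  Only sequences present
#'   in `hits` are returned.
#' @export
split_domains <- function(records, hits, min_nterm = 20) {
  stopifnot(is.data.frame(hits), !anyDuplicated(hits$target_id))
  idx <- match(hits$target_id, records$id)
  if (anyNA(idx)) {
    stop("hit target ", hits$target_id[which(is.na(idx))[1]],
         " not in records")
  }
  len <- nchar(records$residues[idx])
  if (any(hits$env_start > len)) {
    bad <- which(hits$env_start > len)[1]
    stop("corrupt hit: env_start ", hits$env_start[bad],
         " beyond length of ", hits$target_id[bad])
  }
  nterm_len <- hits$env_start - 1L
  has_nterm <- nterm_len >= min_nterm
  data.frame(id = hits$target_id,
             barrel_start = hits$env_start, barrel_end = len,
             nterm_start = ifelse(has_nterm, 1L, NA_integer_),
             nterm_end = ifelse(has_nterm, nterm_len, NA_integer_),
             source_profile = hits$query_profile,
             stringsAsFactors = FALSE)
}

#' Extract region sequences from a partition
#'
#' @param records Sequence data frame.
#' @param partition Output of [split_domains()].
#' @param region `"barrel"` or `"nterm"`.
#' @return Sequence data frame of the region subsequences (ids unchanged);
#'   sequences without the region are omitted.
#' @export
region_records <- function(records, partition, region = c("barrel", "nterm")) {
  region <- match.arg(region)
  s <- if (region == "barrel") partition$barrel_start else partition$nterm_start
  e <- if (region == "barrel") partition$barrel_end else partition$nterm_end
  keep <- !is.na(s)
  idx <- match(partition$id[keep], records$id)
  tax <- if ("taxon_id" %in% names(records)) records$taxon_id[idx] else
    rep("", length(idx))
  data.frame(id = partition$id[keep],
             residues = substr(records$residues[idx], s[keep], e[keep]),
             taxon_id = tax,
             description = rep(paste0(region, " region"), length(idx)),
             stringsAsFactors = FALSE)
}

#' Iterated POTRA scan of an N-terminal region
#'
#' Repeatedly finds the best local hit of the POTRA profile, records its
#' envelope, masks it, and searches again until no hit passes the E-value
#' threshold (per-sequence statistics, database size 1).  Envelopes outside
#' the length band are dropped; survivors are numbered P1..Pk from the
#' N-terminus.
#'
#' @param nterm_residues Residue string of the N-terminal region.
#' @param potra_profile Calibrated `profile_model` for the POTRA repeat.
#' @param min_len,max_len Retention band for segment lengths (defaults 25 and
#'   125 residues, inclusive).
#' @param evalue_threshold Stop when the best remaining hit exceeds this
#'   (default 1e-3).
#' @param id Sequence id copied into the result.
#' @return Data frame: `id`, `index` ("P1", ...), `start`, `end`, `score`
#'   (coordinates within the scanned region, 1-based inclusive).
#' @export
scan_potras <- function(nterm_residues, potra_profile, min_len = 25,
                        max_len = 125, evalue_threshold = 1e-3, id = "seq") {
  stopifnot(inherits(potra_profile, "profile_model"))
  if (is.null(potra_profile$calibration)) stop("POTRA profile not calibrated")
  codes <- encode_residues(nterm_residues)
  maskcode <- match("X", AA21)
  segs <- list()
  repeat {
    al <- cpp_pssm_align(potra_profile$pssm, codes,
                         -potra_profile$gap_open, -potra_profile$gap_extend)
    if (is.na(al$t_start)) break
    ev <- profile_evalue(potra_profile, al$score, 1)
    if (ev > evalue_threshold) break
    segs[[length(segs) + 1L]] <- c(al$t_start, al$t_end, al$score)
    codes[al$t_start:al$t_end] <- maskcode
  }
  if (length(segs) == 0L) {
    return(data.frame(id = character(0), index = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, segs)
  lens <- m[, 2] - m[, 1] + 1
  m <- m[lens >= min_len & lens <= max_len, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(id = character(0), index = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(id = id, index = paste0("P", seq_len(nrow(m))),
             start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             score = m[, 3], stringsAsFactors = FALSE)
}

#' Enforce one POTRA set per cluster
#'
#' Within a cluster the modal segment count k* is determined (ties broken
#' toward the larger count); sequences with more than k* segments keep their
#' k* highest-scoring ones, renumbered from the N-terminus.  Sequences with
#' fewer segments are left unchanged: extra repeats are removed, missing ones
#' are never invented.
#'
#' @param cluster_segments Data frame of POTRA segments (from
#'   [scan_potras()], rows for all sequences of one cluster).
#' @return Data frame of the same shape with trimmed, renumbered segments.
#' @export
consensus_potra_set <- function(cluster_segments) {
  stopifnot(is.data.frame(cluster_segments))
  ids <- unique(cluster_segments$id)
  if (length(ids) == 0L) stop("empty cluster: no POTRA segments")
  counts <- table(factor(cluster_segments$id, levels = ids))
  tab <- table(as.integer(counts))
  best <- max(tab)
  kstar <- max(as.integer(names(tab)[tab == best]))   # tie -> larger count
  out <- lapply(ids, function(one) {
    seg <- cluster_segments[cluster_segments$id == one, , drop = FALSE]
    if (nrow(seg) > kstar) {
      seg <- seg[order(-seg$score), , drop = FALSE][seq_len(kstar), ,
                                                    drop = FALSE]
    }
    seg <- seg[order(seg$start), , drop = FALSE]
    seg$index <- paste0("P", seq_len(nrow(seg)))
    seg
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect a bacterial lipoprotein signal (lipobox)
#'
#' A sequence is called positive when the motif `[LVI][ASTVIG][GAS]C` occurs
#' with its cysteine at a position inside the window and the eight residues
#' preceding the motif have mean Kyte-Doolittle hydropathy above the
#' threshold (the hydrophobic signal core).
#'
#' @param residues Residue string.
#' @param window_start,window_end Allowed cysteine positions (defaults 15 and
#'   40, inclusive).
#' @param min_hydropathy Mean hydropathy required of the eight residues
#'   before the motif (default 1.0).
#' @param id Sequence id copied into the result.
#' @return One-row data frame: `id`, `positive`, `cys_position` (NA when
#'   negative).
#' @export
detect_lipobox <- function(residues, window_start = 15, window_end = 40,
                           min_hydropathy = 1.0, id = "seq") {
  validate_residues(residues, id)
  n <- nchar(residues)
  hits <- gregexpr("(?=[LVI][ASTVIG][GAS]C)", residues, perl = TRUE)[[1]]
  cys <- integer(0)
  if (hits[1] != -1) {
    for (st in as.integer(hits)) {
      cpos <- st + 3L
      if (cpos < window_start || cpos > window_end) next
      if (st <= 8L) next
      core <- substr(residues, st - 8L, st - 1L)
      kd <- mean(KD_HYDROPATHY[strsplit(core, "")[[1]]])
      if (kd > min_hydropathy) cys <- c(cys, cpos)
    }
  }
  data.frame(id = id, positive = length(cys) > 0,
             cys_position = if (length(cys) > 0) cys[1] else NA_integer_,
             stringsAsFactors = FALSE)
}
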