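#' Pairwise alignment parameters
#'
#' Scoring scheme for local protein alignment with affine gaps, plus the
#' Karlin-Altschul constants used to convert raw scores to E-values.  Defaults
#' are BLOSUM62 with gap open 11 / extend 1 and the published gapped constants
#' for that scheme (lambda = 0.267, K = 0.041); they are inputs, not
#' estimated.  A gap of length k costs `gap_open + gap_extend * (k - 1)`.
#'
#' @param matrix Substitution matrix over the 21-letter alphabet (default
#'   [blosum62()] with a score-0 X wildcard).
#' @param gap_open,gap_extend Positive gap penalties, `gap_open >= gap_extend
#'   >= 1`.
#' @param ka_lambda,ka_K Karlin-Altschul constants, both > 0.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                             ka_lambda = 0.267, ka_K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(gap_open >= gap_extend, gap_extend >= 1,
            ka_lambda > 0, ka_K > 0,
            is.matrix(matrix), nrow(matrix) == 21L, ncol(matrix) == 21L)
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 ka_lambda = ka_lambda, ka_K = ka_K),
            class = "alignment_params")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps.  The traceback is deterministic: the end
#' cell is the first maximum in row-major order and ties are resolved
#' diagonal > up > left.  Identity is matches divided by alignment columns,
#' gap columns included.
#'
#' @param a,b Residue strings (upper case; X wildcard scores 0).
#' @param params An [alignment_params()] object.
#' @param id_a,id_b Optional sequence ids copied into the result.
#' @return One-row data frame: `id_a`, `id_b`, `raw_score`, `evalue`,
#'   `identity`, `a_start`, `a_end`, `b_start`, `b_end`, `matches`,
#'   `mismatches`, `gap_opens`, `gaps`, `length` (1-based inclusive
#'   coordinates; NA coordinates when no positive-scoring alignment exists).
#' @export
align_local <- function(a, b, params = alignment_params(),
                        id_a = "a", id_b = "b") {
  validate_residues(a, id_a)
  validate_residues(b, id_b)
  al <- cpp_sw_align(encode_residues(a), encode_residues(b), params$matrix,
                     params$gap_open, params$gap_extend)
  ident <- if (al$length > 0) al$matches / al$length else 0
  data.frame(id_a = id_a, id_b = id_b, raw_score = al$score,
             evalue = evalue_pair(al$score, nchar(a), nchar(b), params),
             identity = ident,
             a_start = al$a_start, a_end = al$a_end,
             b_start = al$b_start, b_end = al$b_end,
             matches = al$matches, mismatches = al$mismatches,
             gap_opens = al$gap_opens, gaps = al$gaps, length = al$length,
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul E-value for a raw local-alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` for sequence lengths m, n.
#'
#' @param raw_score Raw alignment score.
#' @param m,n Lengths of the two sequences (>= 1).
#' @param params An [alignment_params()] object.
#' @return E-value (numeric scalar >= 0).
#' @export
evalue_pair <- function(raw_score, m, n, params = alignment_params()) {
  stopifnot(m >= 1, n >= 1)
  params$ka_K * m * n * exp(-params$ka_lambda * raw_score)
}

#' All-vs-all local alignment hit table
#'
#' Aligns every unordered pair and keeps hits with E-value at or below the
#' cutoff.  Scores are computed with a score-only kernel first; the full
#' traceback (identity, coordinates) is run only for passing pairs.  Output is
#' one row per unordered pair; no self pairs unless `include_self = TRUE`.
#'
#' @param records Sequence data frame.
#' @param params An [alignment_params()] object.
#' @param evalue_cutoff Keep pairs with `evalue <= evalue_cutoff`.
#' @param include_self If TRUE, add a self hit per sequence.
#' @param stats `"full"` (default) runs the traceback for every kept pair,
#'   reporting identity and coordinates; `"score_only"` reports only scores
#'   and E-values (identity and coordinates NA), which is all that graph
#'   building needs and is several-fold faster on large sets.
#' @return Data frame of pair hits as in [align_local()].
#' @export
all_vs_all <- function(records, params = alignment_params(),
                       evalue_cutoff = 1e-5, include_self = FALSE,
                       stats = c("full", "score_only")) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  stats <- match.arg(stats)
  n <- nrow(records)
  codes <- lapply(records$residues, encode_residues)
  lens <- nchar(records$residues)
  scores <- cpp_sw_all_pairs(codes, params$matrix,
                             params$gap_open, params$gap_extend)
  ii <- unlist(lapply(seq_len(n - 1L), function(i) rep(i, n - i)))
  jj <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))
  ev <- params$ka_K * lens[ii] * lens[jj] * exp(-params$ka_lambda * scores)
  keep <- which(ev <= evalue_cutoff)
  if (stats == "score_only") {
    na_row <- function(k, mode = "integer") rep(as.vector(NA, mode), k)
    out <- data.frame(id_a = records$id[ii[keep]],
                      id_b = records$id[jj[keep]],
                      raw_score = scores[keep], evalue = ev[keep],
                      identity = na_row(length(keep), "double"),
                      a_start = na_row(length(keep)),
                      a_end = na_row(length(keep)),
                      b_start = na_row(length(keep)),
                      b_end = na_row(length(keep)),
                      matches = na_row(length(keep)),
                      mismatches = na_row(length(keep)),
                      gap_opens = na_row(length(keep)),
                      gaps = na_row(length(keep)),
                      length = na_row(length(keep)),
                      stringsAsFactors = FALSE)
    if (include_self) {
      self_sc <- vapply(seq_len(n), function(i)
        cpp_sw_score(codes[[i]], codes[[i]], params$matrix,
                     params$gap_open, params$gap_extend), numeric(1))
      out <- rbind(out, data.frame(
        id_a = records$id, id_b = records$id, raw_score = self_sc,
        evalue = params$ka_K * lens * lens *
          exp(-params$ka_lambda * self_sc),
        identity = na_row(n, "double"), a_start = na_row(n),
        a_end = na_row(n), b_start = na_row(n), b_end = na_row(n),
        matches = na_row(n), mismatches = na_row(n),
        gap_opens = na_row(n), gaps = na_row(n), length = na_row(n),
        stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    return(out)
  }
  rows <- lapply(keep, function(k) {
    align_local(records$residues[ii[k]], records$residues[jj[k]], params,
                id_a = records$id[ii[k]], id_b = records$id[jj[k]])
  })
  if (include_self) {
    selfs <- lapply(seq_len(n), function(i) {
      align_local(records$residues[i], records$residues[i], params,
                  id_a = records$id[i], id_b = records$id[i])
    })
    rows <- c(rows, selfs)
  }
  if (length(rows) == 0L) {
    return(align_local("A", "A")[0, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pair hits in 12-column blast-like tabular format
#'
#' Columns: qid, sid, pident, length, mismatches, gapopens, qstart, qend,
#' sstart, send, evalue, bitscore (bit score derived from the raw score via
#' the Karlin-Altschul constants).
#'
#' @param hits Pair-hit data frame from [all_vs_all()].
#' @param path Output TSV path.
#' @param params The [alignment_params()] used to produce the hits.
#' @return Invisibly, `path`.
#' @export
write_pair_hits <- function(hits, path, params = alignment_params()) {
  bit <- (params$ka_lambda * hits$raw_score - log(params$ka_K)) / log(2)
  out <- data.frame(qid = hits$id_a, sid = hits$id_b,
                    pident = round(100 * hits$identity, 2),
                    length = hits$length, mismatches = hits$mismatches,
                    gapopens = hits$gap_opens,
                    qstart = hits$a_start, qend = hits$a_end,
                    sstart = hits$b_start, send = hits$b_end,
                    evalue = signif(hits$evalue, 4),
                    bitscore = round(bit, 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
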