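#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a sequence table.  The id is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' kept as the description.  Residues are upper-cased and validated against
#' the 20-letter amino-acid alphabet (X allowed as wildcard); gap characters
#' are rejected.  Taxon links are carried in side tables, not in FASTA
#' headers, so `taxon_id` is returned empty.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `residues`, `taxon_id`,
#'   `description`, one row per entry in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA entry with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id ", dup[1], " in ", path)
  residues <- toupper(as.character(x))
  for (k in seq_along(residues)) validate_residues(residues[k], ids[k])
  data.frame(id = ids, residues = unname(residues), taxon_id = "",
             description = unname(desc), stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces `x`
#' for valid records.  Sequences are wrapped at 60 columns.
#'
#' @param records Sequence data frame (columns `id`, `residues`, optionally
#'   `description`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(records) == 0L) return(invisible(path))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  lines <- character(0)
  for (k in seq_len(nrow(records))) {
    seqs <- gsub("(.{60})", "\\1\n", records$residues[k])
    seqs <- sub("\n$", "", seqs)
    lines <- c(lines, paste0(">", hdr[k]), strsplit(seqs, "\n")[[1]])
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Collapse exactly identical sequences into duplicate groups
#'
#' Stands in for grouping database entries into 100%-identity clusters:
#' records with byte-identical residue strings form one group, represented by
#' the lexicographically smallest id.
#'
#' @param records Sequence data frame as returned by [read_fasta()].
#' @return A list with `groups` (named list: representative id -> character
#'   vector of member ids, representative included) and `representatives`
#'   (the input rows for the representatives only, in first-occurrence order).
#' @export
collapse_identical <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (anyDuplicated(records$id)) {
    stop("duplicate id ", records$id[duplicated(records$id)][1])
  }
  fac <- factor(records$residues, levels = unique(records$residues))
  members <- split(records$id, fac)
  reps <- vapply(members, function(ids) min(ids), character(1))
  names(members) <- reps
  keep <- records[records$id %in% reps, , drop = FALSE]
  keep <- keep[order(match(keep$residues, levels(fac))), , drop = FALSE]
  rownames(keep) <- NULL
  list(groups = members, representatives = keep)
}

#' Read a taxon table
#'
#' @param path TSV with header `taxon_id`, `name`, `phylum`,
#'   `complete_proteome` (0/1).
#' @return Data frame with `complete_proteome` as logical.
#' @export
read_taxa <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("taxon_id", "name", "phylum", "complete_proteome")
  if (!all(need %in% names(t))) {
    stop("taxon table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(t$taxon_id)) stop("duplicate taxon_id in ", path)
  if (any(!nzchar(t$phylum))) stop("empty phylum in ", path)
  t$complete_proteome <- t$complete_proteome %in% c("1", "TRUE", "true")
  t
}

#' Write a taxon table
#' @param taxa Data frame as from [read_taxa()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_taxa <- function(taxa, path) {
  out <- taxa
  out$complete_proteome <- as.integer(out$complete_proteome)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
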