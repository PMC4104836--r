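#' @useDynLib ompfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 20-letter amino-acid alphabet; "X" is accepted as a wildcard that scores 0
# against every matrix or profile position.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

# Robinson-Robinson amino-acid background frequencies (the composition the
# published Karlin-Altschul constants for BLOSUM62 assume).  Used for random
# sequence generation and as the default profile background.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Kyte-Doolittle hydropathy scale, used by the lipobox detector.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3, X = 0
)

#' Validate a residue string
#'
#' Checks that a sequence uses only the 20 amino-acid letters plus the X
#' wildcard.  Gap characters and anything else are rejected with the 1-based
#' position of the first offender.
#'
#' @param residues Character scalar, upper-case amino-acid sequence.
#' @param id Sequence id used in error messages.
#' @return Invisibly, `residues`.
#' @keywords internal
validate_residues <- function(residues, id = "<sequence>") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("residues must be a single character string (id ", id, ")")
  }
  if (nchar(residues) < 1L) {
    stop("empty sequence for id ", id)
  }
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% AA21))
  if (length(bad) > 0L) {
    stop("illegal residue character '", ch[bad[1]], "' at position ", bad[1],
         " in sequence ", id)
  }
  invisible(residues)
}

# Residue string -> 1-based integer codes into the 21-letter alphabet.
encode_residues <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  codes <- match(ch, AA21)
  if (anyNA(codes)) {
    stop("illegal residue character '", ch[which(is.na(codes))[1]],
         "' at position ", which(is.na(codes))[1])
  }
  codes
}

decode_residues <- function(codes) paste(AA21[codes], collapse = "")

#' BLOSUM62 substitution matrix over the 21-letter alphabet
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, restricted to the 20
#' amino acids and extended with an X row/column of zeros so the wildcard is
#' score-neutral.
#'
#' @return A 21 x 21 integer matrix with dimnames over `A..Y, X`.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA20, AA20]
  out <- matrix(0L, 21L, 21L, dimnames = list(AA21, AA21))
  out[AA20, AA20] <- as.integer(m)
  out
}

# Evaluate a function with a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
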