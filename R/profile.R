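#' Build a position-specific scoring model from a seed alignment
#'
#' Columns of the seed alignment with at least 50% residue occupancy become
#' match columns.  Per-column emission log-odds (bits) follow
#' `log2(((count_r + w * p_r) / (total + w)) / p_r)` with pseudocount weight
#' `w` and background frequencies `p`.  X residues in seeds are ignored
#' (neither counted nor in the total); the X wildcard in targets scores 0 at
#' every column.
#'
#' @param seed_alignment Character vector of aligned sequences (equal length,
#'   `-` or `.` for gaps), or a sequence data frame with a `residues` column.
#' @param pseudocount_weight Total pseudocount mass added per column
#'   (default 5).
#' @param name Profile name.
#' @param background Residue background frequencies (length 20, sums to 1);
#'   default: Robinson-Robinson natural composition.
#' @param gap_open,gap_extend Negative gap scores in bits used when aligning
#'   the profile to targets (defaults -4 and -1).
#' @return An object of class `profile_model` with elements `name`, `pssm`
#'   (match columns x 21 score matrix, X column zero), `gap_open`,
#'   `gap_extend`, `background`, `calibration` (NULL until [calibrate()]).
#' @export
build_profile <- function(seed_alignment, pseudocount_weight = 5,
                          name = "profile", background = NULL,
                          gap_open = -4, gap_extend = -1) {
  if (is.data.frame(seed_alignment)) seed_alignment <- seed_alignment$residues
  stopifnot(is.character(seed_alignment))
  if (length(seed_alignment) < 1L) stop("seed alignment has no sequences")
  seed_alignment <- toupper(seed_alignment)
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1L) {
    stop("seed sequences must have equal padded length")
  }
  if (is.null(background)) background <- AA_BACKGROUND[AA20]
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-9)
  names(background) <- AA20
  mat <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  bad <- !(mat %in% c(AA21, "-", "."))
  if (any(bad)) stop("illegal character '", mat[bad][1], "' in seed alignment")
  occ <- colMeans(matrix(mat %in% AA21, nrow = nrow(mat)))
  match_cols <- which(occ >= 0.5)
  if (length(match_cols) == 0L) stop("seed alignment yields no match columns")
  w <- pseudocount_weight
  pssm <- matrix(0, nrow = length(match_cols), ncol = 21L,
                 dimnames = list(NULL, AA21))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% AA20]            # gaps and X carry no information
    counts <- table(factor(col, levels = AA20))
    total <- sum(counts)
    freq <- (as.numeric(counts) + w * background) / (total + w)
    pssm[k, AA20] <- log2(freq / background)
  }
  structure(list(name = name, pssm = pssm, gap_open = gap_open,
                 gap_extend = gap_extend, background = background,
                 n_match_columns = length(match_cols), calibration = NULL),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model '", x$name, "': ", x$n_match_columns,
      " match columns, gap open/extend ", x$gap_open, "/", x$gap_extend,
      if (is.null(x$calibration)) ", uncalibrated\n" else
        sprintf(", Gumbel(mu = %.2f, lambda = %.3f)\n",
                x$calibration$mu, x$calibration$lambda), sep = "")
  invisible(x)
}

# Best local alignment of a profile against one residue string.
profile_align <- function(profile, residues) {
  cpp_pssm_align(profile$pssm, encode_residues(residues),
                 -profile$gap_open, -profile$gap_extend)
}

#' Sample from / quantiles of the Gumbel (max) distribution
#'
#' `P(S <= s) = exp(-exp(-lambda * (s - mu)))`.
#'
#' @param n Number of draws.
#' @param mu Location. @param lambda Scale slope (> 0).
#' @return Numeric vector of draws.
#' @export
rgumbel <- function(n, mu, lambda) {
  mu - log(-log(stats::runif(n))) / lambda
}

#' Maximum-likelihood fit of a Gumbel distribution
#'
#' Profile likelihood in lambda: solves `1/lambda - mean(x) +
#' sum(x * exp(-lambda x)) / sum(exp(-lambda x)) = 0` by root finding, then
#' `mu = -log(mean(exp(-lambda (x)))) / lambda`.
#'
#' @param x Numeric sample (the distribution of maxima).
#' @return List with `mu`, `lambda`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  if (stats::sd(x) < 1e-12) stop("degenerate scores: all values equal")
  xc <- x - mean(x)                      # center for numerical stability
  g <- function(lam) {
    wexp <- exp(-lam * xc)
    1 / lam + sum(xc * wexp) / sum(wexp)
  }
  # scale is roughly sd * sqrt(6)/pi; bracket widely around it
  s0 <- pi / (stats::sd(x) * sqrt(6))
  lo <- s0 / 50
  hi <- s0 * 50
  lam <- stats::uniroot(g, c(lo, hi), extendInt = "downX", tol = 1e-12)$root
  mu <- mean(x) - log(mean(exp(-lam * xc))) / lam
  list(mu = mu, lambda = lam)
}

#' Calibrate a profile's score statistics on random sequences
#'
#' Scores `n_random` i.i.d. background-random sequences of a fixed length and
#' fits a Gumbel distribution to the optimal local-alignment scores by maximum
#' likelihood.  The fit feeds E-values in [profile_search()].
#'
#' @param profile A `profile_model`.
#' @param n_random Number of random sequences (>= 200; default 500).
#' @param length Length of each random sequence (default 350, a typical
#'   barrel-domain length).
#' @param seed Integer seed; stored with the calibration.
#' @return The profile with a `calibration` list: `mu`, `lambda`,
#'   `n_calibration`, `calibration_length`, `seed`.
#' @export
calibrate <- function(profile, n_random = 500, length = 350, seed = 1) {
  stopifnot(inherits(profile, "profile_model"), n_random >= 200)
  scores <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      s <- paste(sample(AA20, length, replace = TRUE,
                        prob = profile$background), collapse = "")
      profile_align(profile, s)$score
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  if (fit$lambda <= 0) stop("calibration failed: non-positive lambda")
  profile$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                              n_calibration = as.integer(n_random),
                              calibration_length = as.integer(length),
                              seed = as.integer(seed))
  profile
}

# P-value and E-value of a bit score under a profile's Gumbel calibration.
profile_evalue <- function(profile, score, db_size) {
  cal <- profile$calibration
  p <- -expm1(-exp(-cal$lambda * (score - cal$mu)))
  db_size * p
}

#' Search a calibrated profile against a sequence set
#'
#' Computes the best local profile-sequence alignment per target and converts
#' bit scores to E-values via `E = db_size * (1 - exp(-exp(-lambda (S -
#' mu))))`.  The envelope (`env_start`, `env_end`) is the target span of the
#' optimal alignment, 1-based inclusive.
#'
#' @param profile A calibrated `profile_model`.
#' @param records Sequence data frame.
#' @param inclusion_evalue Report hits with `evalue <= inclusion_evalue`.
#' @param db_size Effective database size (default: number of targets).
#' @return Data frame of hits sorted by E-value: `query_profile`,
#'   `target_id`, `score`, `evalue`, `env_start`, `env_end`.
#' @export
profile_search <- function(profile, records, inclusion_evalue = 1,
                           db_size = NULL) {
  stopifnot(inherits(profile, "profile_model"))
  if (is.null(profile$calibration)) {
    stop("profile '", profile$name, "' is not calibrated; run calibrate()")
  }
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (is.null(db_size)) db_size <- nrow(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    al <- profile_align(profile, records$residues[i])
    data.frame(query_profile = profile$name, target_id = records$id[i],
               score = al$score,
               evalue = profile_evalue(profile, al$score, db_size),
               env_start = if (is.na(al$t_start)) NA_integer_ else al$t_start,
               env_end = if (is.na(al$t_end)) NA_integer_ else al$t_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$evalue <= inclusion_evalue, , drop = FALSE]
  out <- out[order(out$evalue, -out$score, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge hit lists from two profiles
#'
#' Union of target ids; where a target was found by both profiles the hit
#' with the higher bit score wins (tie: lower E-value, then lexicographically
#' smaller profile name).
#'
#' @param hits_a,hits_b Hit data frames from [profile_search()].
#' @return A single hit data frame with one row per target id.
#' @export
merge_hits <- function(hits_a, hits_b) {
  all <- rbind(hits_a, hits_b)
  if (nrow(all) == 0L) return(all)
  ord <- order(all$target_id, -all$score, all$evalue, all$query_profile)
  all <- all[ord, , drop = FALSE]
  out <- all[!duplicated(all$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write profile hits as TSV
#' @param hits Hit data frame from [profile_search()] or [merge_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_hits <- function(hits, path) {
  out <- hits
  out$score <- round(out$score, 2)
  out$evalue <- signif(out$evalue, 4)
  names(out) <- c("query", "target", "score_bits", "evalue",
                  "env_start", "env_end")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
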