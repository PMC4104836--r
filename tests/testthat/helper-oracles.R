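# Independent oracle implementations used to check the package's alignment
# and clustering code.  These are written top-down / loop-by-loop from the
# mathematical definitions and share no code with the implementations they
# check.

# ---- local alignment oracles ------------------------------------------------

# Memoized recursive formulation of affine-gap local alignment.  States:
# "M" (last column was a match/mismatch), "A" (gap in b, consuming a),
# "B" (gap in a, consuming b).  A gap of length k costs go + ge*(k-1).
brute_local_score <- function(a, b, sub, go, ge) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  memo <- new.env(parent = emptyenv())
  # best(i, j, s): best score of an alignment ENDING at (i, j) in state s
  best <- function(i, j, s) {
    key <- paste(i, j, s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (s == "M") {
      sc <- sub[av[i], bv[j]]
      prev <- 0
      if (i > 1 && j > 1) {
        prev <- max(0, best(i - 1, j - 1, "M"), best(i - 1, j - 1, "A"),
                    best(i - 1, j - 1, "B"))
      }
      val <- prev + sc
    } else if (s == "A") {
      if (i > 1) {
        val <- max(best(i - 1, j, "M") - go, best(i - 1, j, "A") - ge)
      }
    } else {
      if (j > 1) {
        val <- max(best(i, j - 1, "M") - go, best(i, j - 1, "B") - ge)
      }
    }
    memo[[key]] <- val
    val
  }
  out <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    out <- max(out, best(i, j, "M"))   # optimal local alignments end in M
  }
  out
}

# Explicit enumeration of every local alignment path (no memoization):
# start anywhere, extend by match / gap-in-b / gap-in-a, stop anywhere.
# Exponential; for sequences of length <= 4 only.
enum_local_score <- function(a, b, sub, go, ge) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  walk <- function(i, j, score, state) {
    # i, j: next positions to consume (1-based)
    if (state == "M") best <<- max(best, score)
    if (i <= na && j <= nb) {
      walk(i + 1, j + 1, score + sub[av[i], bv[j]], "M")
    }
    if (i <= na) {
      walk(i + 1, j, score - if (state == "A") ge else go, "A")
    }
    if (j <= nb) {
      walk(i, j + 1, score - if (state == "B") ge else go, "B")
    }
  }
  for (i in seq_len(na)) for (j in seq_len(nb)) walk(i, j, 0, "start")
  best
}

# Brute-force best PSSM local alignment allowing only ungapped alignments and
# alignments with a single gap (in either sequence) of any length.
enum_pssm_score <- function(pssm, target_codes, go, ge) {
  L <- nrow(pssm); nt <- length(target_codes)
  colsc <- function(q, t) pssm[q, target_codes[t]]
  best <- 0
  segscore <- function(q0, t0, len) {
    s <- 0
    for (k in seq_len(len) - 1L) s <- s + colsc(q0 + k, t0 + k)
    s
  }
  for (q0 in seq_len(L)) for (t0 in seq_len(nt)) {
    maxlen <- min(L - q0, nt - t0) + 1L
    for (len in seq_len(maxlen)) {
      best <- max(best, segscore(q0, t0, len))          # ungapped
      # one gap: split the alignment in two segments
      for (cut in seq_len(len - 1L)) for (g in 1:3) {
        gapcost <- go + ge * (g - 1)
        # gap in target (skip g profile columns)
        if (q0 + len - 1L + g <= L) {
          best <- max(best, segscore(q0, t0, cut) +
                        segscore(q0 + cut + g, t0 + cut, len - cut) - gapcost)
        }
        # gap in profile (skip g target residues)
        if (t0 + len - 1L + g <= nt) {
          best <- max(best, segscore(q0, t0, cut) +
                        segscore(q0 + cut, t0 + cut + g, len - cut) - gapcost)
        }
      }
    }
  }
  best
}

# ---- MCL oracle -------------------------------------------------------------

# Literal, loop-based implementation of the Markov-cluster iteration and its
# attractor interpretation; kept independent of the package's vectorized code.
mcl_oracle <- function(n, edges, inflation, expansion = 2,
                       prune = 1e-5, max_iter = 200, tol = 1e-9,
                       selfloop = 1) {
  M <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      M[edges$i[r], edges$j[r]] <- edges$w[r]
      M[edges$j[r], edges$i[r]] <- edges$w[r]
    }
  }
  for (k in seq_len(n)) M[k, k] <- M[k, k] + selfloop
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    prev <- M
    P <- diag(n)
    for (e in seq_len(expansion)) {
      Q <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + P[i, k] * M[k, j]
        Q[i, j] <- acc
      }
      P <- Q
    }
    for (i in seq_len(n)) for (j in seq_len(n)) P[i, j] <- P[i, j] ^ inflation
    for (j in seq_len(n)) P[, j] <- P[, j] / sum(P[, j])
    P[P < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(P[, j])
      if (s == 0) { P[j, j] <- 1; s <- 1 }
      P[, j] <- P[, j] / s
    }
    M <- P
    if (max(abs(M - prev)) < tol) break
  }
  attractors <- which(diag(M) > 0)
  supp <- lapply(attractors, function(a) which(M[a, ] > 0))
  cl_id <- seq_along(attractors)
  if (length(attractors) > 1) {
    repeat {
      changed <- FALSE
      for (x in seq_along(attractors)) for (y in seq_along(attractors)) {
        if (cl_id[x] != cl_id[y] &&
            (length(intersect(supp[[x]], supp[[y]])) > 0 ||
             attractors[x] %in% supp[[y]] || attractors[y] %in% supp[[x]])) {
          cl_id[cl_id == max(cl_id[x], cl_id[y])] <-
            min(cl_id[x], cl_id[y])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (cid in unique(cl_id)) {
    attrs <- attractors[cl_id == cid]
    key <- min(attrs)
    memb <- unique(c(attrs, unlist(supp[cl_id == cid])))
    for (m in memb) {
      assign[m] <- if (is.na(assign[m])) key else min(assign[m], key)
    }
  }
  for (k in seq_len(n)) if (is.na(assign[k])) assign[k] <- k
  # return canonical partition: list of sorted member vectors
  unname(lapply(split(seq_len(n), assign), sort))
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}

# ---- shared study dataset / pipeline (computed once per test run) ----------

.acc_cache <- new.env(parent = emptyenv())

acc_dataset <- function() {
  if (is.null(.acc_cache$data)) {
    .acc_cache$data <- generate_dataset(generator_config(seed = 7))
  }
  .acc_cache$data
}

acc_pipeline <- function() {
  if (is.null(.acc_cache$result)) {
    .acc_cache$result <- run_pipeline(pipeline_config(seed = 7),
                                      data = acc_dataset())
  }
  .acc_cache$result
}

acc_truth_map <- function() {
  d <- acc_dataset()
  stats::setNames(d$truth$template_name, d$truth$id)
}

# adjusted Rand index between two label vectors (independent of any
# clustering package; standard pair-counting formula)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

random_protein <- function(n) {
  paste(sample(names(ompfam:::AA_BACKGROUND), n, replace = TRUE,
               prob = ompfam:::AA_BACKGROUND), collapse = "")
}
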