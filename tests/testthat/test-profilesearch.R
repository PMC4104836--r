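toy_profile <- function(seqs, w = 1, name = "toy") {
  build_profile(seqs, pseudocount_weight = w, name = name)
}

test_that("build_profile applies the occupancy and pseudocount rules", {
  # single-sequence seed: one match column per residue
  p <- toy_profile("ACD")
  expect_equal(p$n_match_columns, 3L)

  # a column with 60% gaps is excluded
  p2 <- toy_profile(c("A-D", "A-D", "ACD", "A-D", "A-D"))
  expect_equal(p2$n_match_columns, 2L)

  # two-sequence seed, column {A, A}: hand-evaluated log-odds
  alpha <- 2.5
  bg <- rep(1 / 20, 20)
  p3 <- build_profile(c("AC", "AC"), pseudocount_weight = alpha,
                      background = bg)
  expected <- log2(((2 + alpha * 0.05) / (2 + alpha)) / 0.05)
  expect_equal(unname(p3$pssm[1, "A"]), expected)

  expect_error(toy_profile(character(0)), "no sequences")
  expect_error(toy_profile(c("--", "--")), "match columns")
  expect_error(toy_profile(c("AC", "ACD")), "equal")
})

test_that("a sequence matching the seed maximises the profile score", {
  p <- calibrate(toy_profile("ACDEFGHIK"), n_random = 200, length = 30,
                 seed = 3)
  self <- ompfam:::profile_align(p, "ACDEFGHIK")$score
  set.seed(8)
  others <- replicate(50, ompfam:::profile_align(p, random_protein(9))$score)
  expect_true(all(others <= self))
})

test_that("Gumbel ML fit recovers parameters and calibration is reproducible", {
  set.seed(1)
  x <- rgumbel(2000, mu = 3, lambda = 1.2)
  f <- fit_gumbel(x)
  expect_lt(abs(f$mu - 3), 0.2)
  expect_lt(abs(f$lambda - 1.2), 0.1)
  expect_error(fit_gumbel(rep(5, 300)), "degenerate")

  p <- toy_profile(c("ACDEFGHIKLMNP", "ACDEFGHIKLMNP"))
  c1 <- calibrate(p, n_random = 250, length = 50, seed = 5)
  c2 <- calibrate(p, n_random = 250, length = 50, seed = 5)
  expect_identical(c1$calibration, c2$calibration)
  expect_gt(c1$calibration$lambda, 0)
  expect_error(calibrate(p, n_random = 100), ">= 200")
})

test_that("search reports envelopes and enforces calibration", {
  seed_seq <- "ACDEFGHIKLMNPQRSTVWY"
  p <- toy_profile(seed_seq)
  recs <- data.frame(id = "t1", residues = seed_seq,
                     stringsAsFactors = FALSE)
  expect_error(profile_search(p, recs), "not calibrated")

  p <- calibrate(p, n_random = 200, length = 60, seed = 4)
  h <- profile_search(p, recs, inclusion_evalue = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$env_start, h$env_end), c(1L, 20L))  # full target covered

  set.seed(17)
  noise <- data.frame(id = "r1", residues = random_protein(200),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(profile_search(p, noise, inclusion_evalue = 1e-5)), 0L)
  # at infinite threshold: one hit per target (self-consistency)
  both <- rbind(recs, noise)
  expect_equal(nrow(profile_search(p, both, inclusion_evalue = Inf)), 2L)
})

test_that("profile alignment equals single-gap enumeration on a toy case", {
  set.seed(23)
  for (k in 1:10) {
    seedseq <- random_protein(5)
    p <- toy_profile(seedseq)
    target <- random_protein(8)
    codes <- ompfam:::encode_residues(target)
    got <- ompfam:::cpp_pssm_align(p$pssm, codes, -p$gap_open,
                                   -p$gap_extend)$score
    want <- enum_pssm_score(p$pssm, codes, -p$gap_open, -p$gap_extend)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("E-values are monotone in score for a fixed calibration", {
  p <- calibrate(toy_profile(c("ACDEFGHIKL", "ACDEFGHIKL")),
                 n_random = 200, length = 40, seed = 6)
  e <- sapply(seq(0, 60, by = 5), function(s)
    ompfam:::profile_evalue(p, s, 100))
  expect_true(all(diff(e) < 0))
})

test_that("envelope containment: trimming outside the envelope keeps the score", {
  d <- acc_dataset()
  sd <- d$seeds$omp85
  p <- calibrate(build_profile(data.frame(id = names(sd),
                                          residues = unname(sd)),
                               5, "omp85"),
                 n_random = 200, length = 350, seed = 9)
  set.seed(12)
  picks <- sample(nrow(d$records), 8)
  for (i in picks) {
    full <- ompfam:::profile_align(p, d$records$residues[i])
    if (is.na(full$t_start)) next
    trimmed <- substr(d$records$residues[i], full$t_start, full$t_end)
    again <- ompfam:::profile_align(p, trimmed)
    expect_gte(again$score + 1e-9, full$score)
  }
})

test_that("merge_hits keeps the higher-scoring result per target", {
  a <- data.frame(query_profile = "p1", target_id = c("t1", "t2"),
                  score = c(60, 40), evalue = c(1e-9, 1e-5),
                  env_start = c(10L, 5L), env_end = c(100L, 80L),
                  stringsAsFactors = FALSE)
  b <- data.frame(query_profile = "p2", target_id = c("t2", "t3"),
                  score = c(50, 30), evalue = c(1e-7, 1e-3),
                  env_start = c(7L, 2L), env_end = c(90L, 60L),
                  stringsAsFactors = FALSE)
  m <- merge_hits(a, b)
  expect_setequal(m$target_id, c("t1", "t2", "t3"))   # set-union oracle
  t2 <- m[m$target_id == "t2", ]
  expect_equal(t2$query_profile, "p2")                # 50 beats 40
  expect_equal(t2$env_start, 7L)                      # envelope travels along
  only <- m[m$target_id == "t1", ]
  expect_equal(only$score, 60)
})
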