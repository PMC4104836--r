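test_that("domain library is deterministic and respects stated geometry", {
  lib1 <- make_domain_library(1)
  lib2 <- make_domain_library(1)
  expect_identical(lib1, lib2)
  expect_false(identical(lib1, make_domain_library(2)))

  expect_equal(nchar(lib1$barrel_omp85), 380L)
  expect_equal(nchar(lib1$barrel_tpsb), 300L)
  expect_true(nchar(lib1$potra) >= 25 && nchar(lib1$potra) <= 125)
  expect_match(lib1$lipobox_signal, "[LVI][ASTVI][GAS]C$")

  # the two barrel classes share intermediate identity, computed with the
  # pairwise module on the emitted pair
  h <- align_local(lib1$barrel_omp85, lib1$barrel_tpsb)
  expect_gte(h$identity, 0.30)
  expect_lte(h$identity, 0.55)
  # and differ at >= 30% of aligned positions
  expect_gte(1 - h$identity, 0.30)
})

test_that("architecture templates satisfy their invariants", {
  t <- architecture_templates()
  expect_true(all(t$potra_count >= 0 & t$potra_count <= 5))
  expect_true(all(t$barrel_class != "none" | t$name == "FtsQ_outgroup"))
  expect_true(all(!t$lipobox | t$potra_count >= 1))
})

test_that("zero-noise sampling reproduces the template consensus exactly", {
  lib <- make_domain_library(3)
  tmpl <- architecture_templates()
  for (nm in c("BamA", "Lipo", "noNterm")) {
    t <- as.list(tmpl[tmpl$name == nm, ])
    set.seed(1)
    draw <- sample_sequence(t, lib, divergence = 0, indel_rate = 0)
    expect_equal(draw$record$residues, template_consensus(t, lib))
    dm <- parse_truth_domains(draw$truth$domains)
    if (nm == "noNterm") {
      expect_equal(dm$kind, "barrel")          # exactly one domain
      expect_equal(dm$start, 1L)
    }
    # truth coordinates legal: sorted, in range, non-overlapping
    expect_true(all(diff(dm$start) > 0))
    expect_true(all(dm$end >= dm$start))
    expect_lte(max(dm$end), nchar(draw$record$residues))
    expect_true(all(dm$start[-1] > dm$end[-nrow(dm)]))
  }
})

test_that("per-site divergence hits the binomial expectation", {
  lib <- make_domain_library(5)
  tmpl <- architecture_templates()
  t <- as.list(tmpl[tmpl$name == "TamA", ])
  cons <- strsplit(template_consensus(t, lib), "")[[1]]
  set.seed(9)
  match_frac <- replicate(300, {
    draw <- sample_sequence(t, lib, divergence = 0.3, indel_rate = 0)
    mean(strsplit(draw$record$residues, "")[[1]] == cons)
  })
  expect_lt(abs(mean(match_frac) - 0.70), 0.03)
})

test_that("generate_dataset emits consistent counts and legal truth", {
  d <- acc_dataset()
  expect_equal(nrow(d$records), 350L)           # 10 x 30 + 50 contaminants
  expect_equal(nrow(d$truth), 350L)
  expect_equal(sum(startsWith(d$truth$template_name, "Contaminant")), 50L)
  counts <- table(d$truth$template_name)
  expect_true(all(counts[ompfam:::DEFAULT_FAMILIES] == 30L))
  expect_setequal(d$records$id, d$truth$id)
  for (k in sample(nrow(d$truth), 25)) {
    dm <- parse_truth_domains(d$truth$domains[k])
    len <- nchar(d$records$residues[d$records$id == d$truth$id[k]])
    expect_true(all(dm$start >= 1 & dm$end <= len & dm$start <= dm$end))
    if (nrow(dm) > 1) expect_true(all(dm$start[-1] > dm$end[-nrow(dm)]))
  }
  # seed alignments are ungapped, equal-length blocks
  for (s in d$seeds) {
    expect_true(length(unique(nchar(s))) == 1L)
    expect_false(any(grepl("-", s, fixed = TRUE)))
  }
})

test_that("identical config and seed give byte-identical files", {
  cfg <- generator_config(templates = c(BamA = 4, noNterm = 3),
                          n_contaminants = 4, n_contaminant_families = 2,
                          seed = 11)
  d1 <- generate_dataset(cfg, outdir = withr::local_tempdir())
  d2 <- generate_dataset(cfg, outdir = withr::local_tempdir())
  for (f in c("sequences", "truth", "taxa", "annotations")) {
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]))
  }
  expect_identical(readLines(d1$paths$seed_omp85),
                   readLines(d2$paths$seed_omp85))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(templates = c(BamA = 0)), "count 0")
  expect_error(generator_config(templates = c(NotAFamily = 5)), "unknown")
  expect_error(generator_config(divergence = 0.95))
})

test_that("contaminant members carry a weak barrel-like segment", {
  d <- acc_dataset()
  lib <- d$library
  ids <- d$truth$id[d$truth$template_name == "Contaminant_1"]
  idents <- vapply(ids[1:5], function(i) {
    align_local(d$records$residues[d$records$id == i],
                lib$barrel_omp85)$identity
  }, numeric(1))
  # weak partial similarity: clearly above random, clearly below family level
  expect_gt(mean(idents), 0.2)
  expect_lt(mean(idents), 0.5)
})
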