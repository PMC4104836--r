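mk_hit <- function(id, env_start, env_end, profile = "omp85") {
  data.frame(query_profile = profile, target_id = id, score = 100,
             evalue = 1e-20, env_start = env_start, env_end = env_end,
             stringsAsFactors = FALSE)
}

test_that("split_domains partitions at the envelope start", {
  recs <- data.frame(id = c("a", "b", "c"),
                     residues = c(random_protein(500), random_protein(400),
                                  random_protein(300)),
                     stringsAsFactors = FALSE)
  hits <- rbind(mk_hit("a", 150L, 480L), mk_hit("b", 15L, 380L),
                mk_hit("c", 21L, 290L))
  part <- split_domains(recs, hits, min_nterm = 20)
  a <- part[part$id == "a", ]
  expect_equal(c(a$barrel_start, a$barrel_end), c(150L, 500L))
  expect_equal(c(a$nterm_start, a$nterm_end), c(1L, 149L))
  b <- part[part$id == "b", ]
  expect_true(is.na(b$nterm_start))            # 14 < 20: absent
  expect_equal(b$barrel_start, 15L)            # still in barrel analyses
  cc <- part[part$id == "c", ]
  expect_equal(c(cc$nterm_start, cc$nterm_end), c(1L, 20L))  # exactly 20 kept

  expect_error(split_domains(recs, mk_hit("c", 400L, 420L)), "corrupt hit")
})

test_that("region extraction tiles the sequence prefix and suffix exactly", {
  recs <- data.frame(id = "a", residues = random_protein(500),
                     stringsAsFactors = FALSE)
  part <- split_domains(recs, mk_hit("a", 150L, 480L))
  barrel <- region_records(recs, part, "barrel")
  nterm <- region_records(recs, part, "nterm")
  expect_equal(paste0(nterm$residues, barrel$residues), recs$residues)
})

test_that("iterated POTRA scan recovers planted repeats exactly at zero noise", {
  d0 <- generate_dataset(generator_config(seed = 7, divergence = 0,
                                          indel_rate = 0))
  sd <- d0$seeds$potra
  pp <- calibrate(build_profile(data.frame(id = names(sd),
                                           residues = unname(sd)),
                                5, "potra"),
                  n_random = 250, length = 350, seed = 42)
  for (fam in c("TamA", "BamA", "noNterm")) {
    id <- d0$truth$id[d0$truth$template_name == fam][1]
    dm <- parse_truth_domains(d0$truth$domains[d0$truth$id == id])
    barrel_start <- dm$start[dm$kind == "barrel"]
    nterm <- substr(d0$records$residues[d0$records$id == id], 1,
                    barrel_start - 1)
    planted <- dm[dm$kind == "potra", ]
    if (nchar(nterm) == 0) {             # noNterm: nothing to scan
      expect_equal(nrow(planted), 0L)
      next
    }
    seg <- scan_potras(nterm, pp, id = id)
    expect_equal(nrow(seg), nrow(planted))
    expect_equal(seg$start, planted$start)
    expect_equal(seg$end, planted$end)
    expect_equal(seg$index, paste0("P", seq_len(nrow(seg))))
  }
})

test_that("scan segments respect the length band and ordering", {
  res <- acc_pipeline()
  seglen <- res$potras$end - res$potras$start + 1
  expect_true(all(seglen >= 25 & seglen <= 125))
  for (one in split(res$potras, res$potras$id)) {
    expect_true(all(diff(one$start) > 0))
    expect_true(all(one$start[-1] > one$end[-nrow(one)]))  # non-overlapping
    expect_equal(one$index, paste0("P", seq_len(nrow(one))))
  }
})

test_that("consensus_potra_set trims to the modal count, never invents", {
  seg <- function(id, n, scores = seq_len(n)) {
    data.frame(id = id, index = paste0("P", seq_len(n)),
               start = seq(1, by = 100, length.out = n),
               end = seq(80, by = 100, length.out = n),
               score = scores, stringsAsFactors = FALSE)
  }
  # counts {5,5,5,6}: the 6-count sequence is trimmed to its best 5
  segs <- rbind(seg("a", 5), seg("b", 5), seg("c", 5),
                seg("d", 6, c(9, 1, 8, 7, 6, 5)))
  out <- consensus_potra_set(segs)
  cnt <- table(out$id)
  expect_true(all(cnt == 5))
  d <- out[out$id == "d", ]
  expect_false(101 %in% d$start)                 # the weakest was dropped
  expect_equal(d$index, paste0("P", 1:5))        # renumbered N->C

  # identity case
  same <- rbind(seg("a", 3), seg("b", 3), seg("c", 3))
  expect_equal(consensus_potra_set(same), same)

  # modal tie {2,2,3,3}: larger count wins, nothing trimmed
  tie <- rbind(seg("a", 2), seg("b", 2), seg("c", 3), seg("d", 3))
  out2 <- consensus_potra_set(tie)
  expect_equal(as.vector(table(out2$id)[c("a", "b", "c", "d")]),
               c(2L, 2L, 3L, 3L))

  # never increases any sequence's count
  expect_true(all(table(out2$id) <= table(tie$id)))
  expect_error(consensus_potra_set(segs[0, ]), "empty cluster")
})

test_that("lipobox detection follows the motif, window, and hydropathy rules", {
  lib <- make_domain_library(7)
  tmpl <- architecture_templates()
  lipo <- as.list(tmpl[tmpl$name == "Lipo", ])
  set.seed(2)
  s <- sample_sequence(lipo, lib, divergence = 0, indel_rate = 0)
  call <- detect_lipobox(s$record$residues)
  expect_true(call$positive)
  expect_equal(call$cys_position, 20L)
  expect_true(call$cys_position >= 15 && call$cys_position <= 40)

  # no cysteine in the first 40 residues: negative
  nocys <- gsub("C", "A", random_protein(100))
  expect_false(detect_lipobox(nocys)$positive)

  # motif with the cysteine outside the window: negative
  seqs <- paste0(strrep("A", 26), "LLLLLLLL", "LAGC", strrep("A", 40))
  expect_equal(nchar(sub("C.*", "C", seqs)), 38L)
  expect_false(detect_lipobox(seqs, 15, 30)$positive)
  expect_true(detect_lipobox(seqs, 15, 40)$positive)

  # hydrophilic stretch before the motif: negative
  polar <- paste0(strrep("A", 12), "DEDEDEDE", "LAGC", strrep("A", 40))
  expect_false(detect_lipobox(polar)$positive)
})
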