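test_that("components match brute-force reachability", {
  # edgeless and complete graphs
  gempty <- build_graph(data.frame(id_a = character(0), id_b = character(0),
                                   evalue = numeric(0)),
                        nodes = c("a", "b", "c"))
  expect_equal(network_components(gempty), list("a", "b", "c"))

  ids <- sprintf("n%d", 1:5)
  pairs <- t(combn(ids, 2))
  gfull <- build_graph(data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                                  evalue = 1e-10), nodes = ids)
  expect_equal(network_components(gfull), list(sort(ids)))

  # random graphs vs transitive-closure oracle
  set.seed(19)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    ids <- sprintf("v%02d", seq_len(n))
    pr <- t(combn(ids, 2))
    pick <- stats::runif(nrow(pr)) < 0.25
    g <- build_graph(data.frame(id_a = pr[pick, 1], id_b = pr[pick, 2],
                                evalue = rep(1e-8, sum(pick))), nodes = ids)
    # reachability closure
    adj <- diag(n) > 0
    for (r in which(pick)) {
      i <- match(pr[r, 1], ids); j <- match(pr[r, 2], ids)
      adj[i, j] <- adj[j, i] <- TRUE
    }
    for (rep in seq_len(n)) adj <- adj | (adj %*% adj > 0)
    oracle <- unique(apply(adj, 1, function(row) sort(ids[row]),
                           simplify = FALSE))
    oracle <- oracle[order(vapply(oracle, min, character(1)))]
    expect_equal(network_components(g), oracle)
  }
})

test_that("networks carry attributes, drop self-loops, reduce to centroids", {
  set.seed(23)
  fam1 <- random_protein(90)
  fam2 <- random_protein(90)
  recs <- data.frame(id = sprintf("s%d", 1:6),
                     residues = c(fam1, fam1, fam1, fam2, fam2, fam2),
                     stringsAsFactors = FALSE)
  attrs <- data.frame(id = recs$id,
                      subfamily = rep(c("f1", "f2"), each = 3),
                      stringsAsFactors = FALSE)
  net <- build_network(recs, identity_reduction = 0.8, evalue_cutoff = 1e-5,
                       attributes = attrs)
  # identical copies collapse onto one centroid per family
  expect_equal(length(net$graph$nodes), 2L)
  expect_false(any(net$graph$edges$i == net$graph$edges$j))
  expect_setequal(net$nodes$subfamily, c("f1", "f2"))
  # zero cross-family hits: families end up in different components
  expect_equal(length(network_components(net)), 2L)

  one <- build_network(recs[1, , drop = FALSE], identity_reduction = NULL)
  expect_equal(nrow(one$graph$edges), 0L)
})

test_that("presence matrix matches hand-computed percentages", {
  taxa <- data.frame(
    taxon_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    name = paste("sp", 1:6),
    phylum = c("P1", "P1", "P2", "P2", "P3", "P3"),
    complete_proteome = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    id = sprintf("g%d", 1:6),
    subfamily = c("A", "A", "B", "A", "B", "B"),
    taxon_id = c("t1", "t2", "t1", "t3", "t4", "t5"),
    stringsAsFactors = FALSE)
  m <- presence_matrix(assignments, taxa)
  expect_equal(m["P1", "A"], 100)       # both complete genomes carry A
  expect_equal(m["P1", "B"], 50)        # one of two
  expect_equal(m["P2", "A"], 100)       # t3 only; t4 not complete
  expect_equal(m["P2", "B"], 0)         # t4's B is excluded: 0% endpoint
  expect_true(all(is.na(m["P3", ])))    # no complete genomes: missing, not 0

  # indicator aggregation of copy_numbers reproduces the matrix
  cn <- copy_numbers(assignments, taxa)
  for (p in c("P1", "P2")) {
    genomes <- taxa$taxon_id[taxa$phylum == p & taxa$complete_proteome]
    for (f in colnames(m)) {
      expect_equal(m[p, f],
                   100 * sum(cn[genomes, f] > 0) / length(genomes))
    }
  }
})

test_that("copy numbers count paralogs over complete proteomes only", {
  taxa <- data.frame(taxon_id = c("t1", "t2"), name = c("a", "b"),
                     phylum = "P", complete_proteome = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  assignments <- data.frame(id = c("g1", "g2", "g3"),
                            subfamily = c("BamA", "BamA", "TamA"),
                            taxon_id = c("t1", "t1", "t2"),
                            stringsAsFactors = FALSE)
  cn <- copy_numbers(assignments, taxa)
  expect_equal(cn["t1", "BamA"], 2L)    # two paralogs
  expect_equal(cn["t1", "TamA"], 0L)    # absent subfamily
  expect_false("t2" %in% rownames(cn))  # incomplete proteome excluded
  expect_equal(sum(cn[, "BamA"]), 2L)   # marginal-sum oracle
})

test_that("network export writes loadable edge and node tables", {
  recs <- data.frame(id = c("a", "b"), residues = rep(random_protein(80), 2),
                     stringsAsFactors = FALSE)
  net <- build_network(recs, identity_reduction = NULL, evalue_cutoff = 1e-3,
                       attributes = data.frame(id = c("a", "b"),
                                               subfamily = "f",
                                               stringsAsFactors = FALSE))
  fe <- withr::local_tempfile(); fn <- withr::local_tempfile()
  write_network(net, fe, fn)
  edges <- read.delim(fe)
  expect_equal(names(edges), c("source", "target", "weight"))
  nodes <- read.delim(fn)
  expect_equal(nodes$subfamily, c("f", "f"))
})
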