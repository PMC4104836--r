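Package: ompfam
Title: Classification of the Omp85/TpsB Outer-Membrane Protein Superfamily
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully scripted re-implementation of the multi-stage
    procedure used to resolve the Omp85/TpsB outer-membrane protein superfamily
    into subfamilies: profile-based candidate detection with extreme-value
    E-value calibration, exact-duplicate collapse, Markov clustering of
    all-vs-all similarity graphs, cluster-level contaminant curation, greedy
    centroid reduction, envelope-based barrel/N-terminus partitioning, POTRA
    repeat extraction, lipoprotein-signal (lipobox) detection, sequence
    similarity networks, and taxonomic distribution matrices.  A synthetic
    superfamily generator with ground-truth annotations stands in for a live
    protein database so every stage can be exercised and tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
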