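# Synthetic superfamily generator.
#
# The generator emulates a bacterial outer-membrane protein superfamily built
# around a conserved beta-barrel: ten subfamily architectures (POTRA repeat
# counts 0-5, optional accessory domains, a lipoprotein signal), two divergent
# barrel classes, contaminant families with a weak partial barrel match, and a
# phylum-structured taxon table.  Every sequence carries a ground-truth record
# (template, domain coordinates, taxon) so downstream stages can be scored.
#
# Two levels of divergence shape the data.  Each subfamily owns fixed
# "signature" variants of the shared domain consensi (strong for barrels,
# milder for POTRA repeats, derived deterministically from the library seed);
# individual sequences are then sampled around their subfamily consensus at
# the configured per-site divergence.  Subfamilies are therefore mutually
# recognisable through profiles built from multi-family seed alignments while
# remaining separable in pairwise similarity space -- the situation the
# classification pipeline is designed for.

BARREL_SIGNATURE_DIVERGENCE <- 0.60   # subfamily barrel/contaminant signatures
POTRA_SIGNATURE_DIVERGENCE <- 0.43    # subfamily POTRA signatures
LINKER_LENGTH <- 8L

# Lipobox position classes; the terminal cysteine is invariant.
LIPOBOX_CLASSES <- list(c("L", "V", "I"), c("A", "S", "T", "V", "I"),
                        c("G", "A", "S"), "C")

derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Substitutions and fresh residues are drawn from the natural (Robinson-
# Robinson) composition so the published Karlin-Altschul statistics apply to
# the generated sequences.
mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    keep <- names(AA_BACKGROUND) != chars[i]
    chars[i] <- sample(names(AA_BACKGROUND)[keep], 1L,
                       prob = AA_BACKGROUND[keep])
  }
  chars
}

random_chars <- function(n) {
  sample(names(AA_BACKGROUND), n, replace = TRUE, prob = AA_BACKGROUND)
}

#' Build the synthetic domain consensus library
#'
#' Deterministically (given the seed) constructs consensus residue strings for
#' every domain kind: two barrel classes sharing roughly 40% identity
#' (`barrel_omp85`, 380 aa; `barrel_tpsb`, 300 aa), a 75-aa POTRA repeat
#' (inside the 25-125 aa retention band), accessory domains (`wd40` 280 aa,
#' `patatin` 230 aa, `metallo` 150 aa), a 180-aa divisome-protein tail
#' (`ftsq_tail`), and a 20-aa lipoprotein signal ending in the lipobox motif
#' `[LVI][ASTVI][GAS]C` over a hydrophobic core.
#'
#' @param seed Integer seed.
#' @return Named list of consensus residue strings, with the seed attached as
#'   an attribute.
#' @export
make_domain_library <- function(seed = 1) {
  with_seed(derive_seed(seed, "library"), {
    omp85 <- random_chars(380L)
    tpsb <- mutate_chars(omp85[1:300], 0.55)
    hydro <- c("L", "I", "V", "F")   # strongly hydrophobic signal core
    polar <- c("K", "R", "S", "T", "N", "Q")
    signal <- c("M", sample(polar, 7L, replace = TRUE),
                sample(hydro, 8L, replace = TRUE), "L", "A", "G", "C")
    lib <- list(
      barrel_omp85 = paste(omp85, collapse = ""),
      barrel_tpsb = paste(tpsb, collapse = ""),
      potra = paste(random_chars(75L), collapse = ""),
      wd40 = paste(random_chars(280L), collapse = ""),
      patatin = paste(random_chars(230L), collapse = ""),
      metallo = paste(random_chars(150L), collapse = ""),
      ftsq_tail = paste(random_chars(180L), collapse = ""),
      lipobox_signal = paste(signal, collapse = "")
    )
    attr(lib, "seed") <- seed
    lib
  })
}

#' Subfamily architecture templates
#'
#' The ten bacterial subfamily architectures plus the cyanobacterial barrel
#' variant and the POTRA-bearing divisome outgroup.  Contaminant templates are
#' created separately by [generate_dataset()].
#'
#' @return Data frame: `name`, `barrel_class` (omp85/tpsb/none),
#'   `potra_count`, `accessory_domain`, `lipobox`.
#' @export
architecture_templates <- function() {
  data.frame(
    name = c("BamA", "BamA_cyano", "TamA", "BamA_like", "Lipo", "WD40",
             "Patatin", "Metallo", "noNterm", "FhaC", "Hmw1B",
             "FtsQ_outgroup"),
    barrel_class = c("omp85", "omp85", "omp85", "omp85", "omp85", "omp85",
                     "omp85", "omp85", "omp85", "tpsb", "omp85", "none"),
    potra_count = c(5L, 3L, 3L, 2L, 3L, 0L, 1L, 0L, 0L, 2L, 2L, 1L),
    accessory_domain = c("none", "none", "none", "none", "none", "wd40",
                         "patatin", "metallo", "none", "none", "none",
                         "none"),
    lipobox = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

DEFAULT_FAMILIES <- c("BamA", "TamA", "BamA_like", "Lipo", "WD40", "Patatin",
                      "Metallo", "noNterm", "FhaC", "Hmw1B")

# Subfamily-specific variant of a base consensus, deterministic in
# (library seed, template, part key).
signature_variant <- function(library, template_name, key, base, rate) {
  with_seed(derive_seed(attr(library, "seed"),
                        paste(template_name, key, sep = "/")), {
    paste(mutate_chars(strsplit(base, "", fixed = TRUE)[[1]], rate),
          collapse = "")
  })
}

# Ordered parts (kind, residues) for one template, linkers included.
# Domain order: signal?, accessory?, POTRA repeats, barrel; N-terminal
# extensions always precede the barrel.
template_parts <- function(template, library) {
  stopifnot(is.list(template) || is.data.frame(template))
  t <- as.list(template)
  parts <- list()
  add <- function(kind, residues) {
    parts[[length(parts) + 1L]] <<- list(kind = kind, residues = residues)
  }
  linker <- function(k) {
    with_seed(derive_seed(attr(library, "seed"),
                          paste(t$name, "linker", k, sep = "/")), {
      paste(random_chars(LINKER_LENGTH), collapse = "")
    })
  }
  nlink <- 0L
  add_linker <- function() {
    nlink <<- nlink + 1L
    add("linker", linker(nlink))
  }
  if (isTRUE(t$lipobox)) add("signal", library$lipobox_signal)
  if (t$accessory_domain != "none") {
    if (length(parts) > 0L) add_linker()
    add(t$accessory_domain, library[[t$accessory_domain]])
  }
  if (t$potra_count > 0L) {
    potra_var <- signature_variant(library, t$name, "potra", library$potra,
                                   POTRA_SIGNATURE_DIVERGENCE)
    for (k in seq_len(t$potra_count)) {
      if (length(parts) > 0L) add_linker()
      add("potra", potra_var)
    }
  }
  if (t$barrel_class != "none") {
    base <- if (t$barrel_class == "omp85") library$barrel_omp85 else
      library$barrel_tpsb
    if (length(parts) > 0L) add_linker()
    add("barrel", signature_variant(library, t$name, "barrel", base,
                                    BARREL_SIGNATURE_DIVERGENCE))
  }
  if (identical(t$name, "FtsQ_outgroup")) {
    add_linker()
    add("ftsq_tail", library$ftsq_tail)
  }
  parts
}

#' Concatenated subfamily consensus for a template
#'
#' The sequence a template produces at zero divergence: its subfamily domain
#' variants joined by the template's fixed linkers.
#'
#' @param template One row of [architecture_templates()] (or a compatible
#'   list, e.g. a contaminant template).
#' @param library A domain library from [make_domain_library()].
#' @return Residue string.
#' @export
template_consensus <- function(template, library) {
  paste(vapply(template_parts(template, library), `[[`, character(1),
               "residues"), collapse = "")
}

# Contaminant template: unrelated 350-aa ancestor carrying a ~60-residue
# segment weakly similar to the omp85 barrel, so the permissive profile
# search recovers it while subfamily clustering rejects it.
contaminant_template <- function(k, library,
                                 segment_length = 60L,
                                 segment_divergence = 0.60) {
  name <- paste0("Contaminant_", k)
  ancestor <- with_seed(derive_seed(attr(library, "seed"), name), {
    chars <- random_chars(350L)
    seg <- strsplit(substr(library$barrel_omp85, 101L,
                           100L + segment_length), "", fixed = TRUE)[[1]]
    chars[101:(100L + segment_length)] <- mutate_chars(seg,
                                                       segment_divergence)
    paste(chars, collapse = "")
  })
  list(name = name, barrel_class = "none", potra_count = 0L,
       accessory_domain = "none", lipobox = FALSE, ancestor = ancestor)
}

# Parts for a contaminant: one opaque block (no annotated domains).
contaminant_parts <- function(template) {
  list(list(kind = "contaminant_body", residues = template$ancestor))
}

#' Sample one sequence from a template
#'
#' Each consensus position is substituted independently with probability
#' `divergence`; the four lipobox motif positions are constrained to
#' class-preserving substitutions (the cysteine is invariant) since the motif
#' is under functional constraint.  Indels are applied inside linkers only by
#' default so that ground-truth domain coordinates remain exact;
#' `indels_in_domains = TRUE` lifts this for stress tests.  Uses the current
#' RNG state; seed the RNG (or use [generate_dataset()]) for reproducibility.
#'
#' @param template Template row/list (see [architecture_templates()]).
#' @param library Domain library.
#' @param divergence Per-site substitution probability in `[0, 0.9)`.
#' @param indel_rate Per-site indel probability (linkers only by default).
#' @param id Sequence id.
#' @param taxon_id Taxon link recorded in the truth record.
#' @param indels_in_domains Allow indels inside domains.
#' @return List with `record` (one-row sequence data frame) and `truth`
#'   (one-row data frame: `id`, `template_name`, `taxon_id`, `domains` as
#'   `kind:start-end` separated by `;`).
#' @export
sample_sequence <- function(template, library, divergence = 0.25,
                            indel_rate = 0.01, id = "seq", taxon_id = "",
                            indels_in_domains = FALSE) {
  stopifnot(divergence >= 0, divergence < 0.9)
  t <- as.list(template)
  parts <- if (!is.null(t$ancestor)) contaminant_parts(t) else
    template_parts(t, library)
  out <- character(length(parts))
  coords <- list()
  pos <- 0L
  for (pi in seq_along(parts)) {
    p <- parts[[pi]]
    chars <- strsplit(p$residues, "", fixed = TRUE)[[1]]
    if (p$kind == "signal" && divergence > 0) {
      n <- length(chars)
      motif_idx <- (n - 3L):n
      plain <- chars[-motif_idx]
      chars[-motif_idx] <- mutate_chars(plain, divergence)
      for (m in seq_along(motif_idx)) {
        cls <- LIPOBOX_CLASSES[[m]]
        if (length(cls) > 1L && stats::runif(1) < divergence) {
          chars[motif_idx[m]] <- sample(setdiff(cls, chars[motif_idx[m]]), 1L)
        }
      }
    } else {
      chars <- mutate_chars(chars, divergence)
    }
    if (indel_rate > 0 && (p$kind == "linker" || indels_in_domains)) {
      keep <- stats::runif(length(chars)) >= indel_rate / 2
      chars <- chars[keep]
      ins <- stats::runif(length(chars)) < indel_rate / 2
      if (any(ins)) {
        newc <- character(0)
        for (ci in seq_along(chars)) {
          newc <- c(newc, chars[ci])
          if (ins[ci]) newc <- c(newc, sample(AA20, 1L))
        }
        chars <- newc
      }
    }
    out[pi] <- paste(chars, collapse = "")
    if (!(p$kind %in% c("linker"))) {
      coords[[length(coords) + 1L]] <-
        list(kind = p$kind, start = pos + 1L, end = pos + length(chars))
    }
    pos <- pos + length(chars)
  }
  domains <- vapply(coords, function(cc)
    paste0(cc$kind, ":", cc$start, "-", cc$end), character(1))
  list(
    record = data.frame(id = id, residues = paste(out, collapse = ""),
                        taxon_id = taxon_id,
                        description = paste("template", t$name),
                        stringsAsFactors = FALSE),
    truth = data.frame(id = id, template_name = t$name, taxon_id = taxon_id,
                       domains = paste(domains, collapse = ";"),
                       stringsAsFactors = FALSE))
}

#' Parse a truth `domains` string
#' @param domains A `kind:start-end;...` string from a truth record.
#' @return Data frame `kind`, `start`, `end`.
#' @export
parse_truth_domains <- function(domains) {
  items <- strsplit(domains, ";", fixed = TRUE)[[1]]
  m <- regmatches(items, regexec("^([a-z0-9_]+):(\\d+)-(\\d+)$", items))
  data.frame(kind = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defaults define the reference synthetic study: 10 subfamilies of 30
#' sequences each, 50 contaminants in 5 families, per-site divergence 0.25,
#' indels confined to linkers, 4 phyla of 5 taxa (4 of 5 flagged complete
#' proteomes), the Lipo subfamily confined to (and present throughout) one
#' phylum, and 30% of annotation labels masked to "unknown".
#'
#' @param templates Named integer vector: sequences per subfamily template.
#' @param divergence Per-site substitution probability.
#' @param indel_rate Per-site indel probability (linkers only).
#' @param n_contaminant_families,n_contaminants Contaminant layout.
#' @param unknown_fraction Fraction of annotation labels masked to "unknown".
#' @param n_ftsq Number of divisome-outgroup (FtsQ-like) sequences (kept out
#'   of the superfamily dataset; used only for POTRA network context).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(templates = NULL, divergence = 0.25,
                             indel_rate = 0.01, n_contaminant_families = 5L,
                             n_contaminants = 50L, unknown_fraction = 0.3,
                             n_ftsq = 0L, seed = 1L) {
  if (is.null(templates)) {
    templates <- stats::setNames(rep(30L, length(DEFAULT_FAMILIES)),
                                 DEFAULT_FAMILIES)
  }
  known <- architecture_templates()$name
  if (!all(names(templates) %in% known)) {
    stop("unknown template(s): ",
         paste(setdiff(names(templates), known), collapse = ", "))
  }
  if (any(templates <= 0)) {
    stop("template referenced with count 0: ",
         paste(names(templates)[templates <= 0], collapse = ", "))
  }
  stopifnot(divergence >= 0, divergence < 0.9, indel_rate >= 0,
            n_contaminant_families >= 0, n_contaminants >= 0,
            unknown_fraction >= 0, unknown_fraction <= 1)
  structure(list(templates = templates, divergence = divergence,
                 indel_rate = indel_rate,
                 n_contaminant_families = as.integer(n_contaminant_families),
                 n_contaminants = as.integer(n_contaminants),
                 unknown_fraction = unknown_fraction,
                 n_ftsq = as.integer(n_ftsq),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Default phylum layout: which phyla may carry each subfamily.  The Lipo
# subfamily is confined to Bacteroidetes and seeded into every one of its
# taxa; BamA is ubiquitous.
default_phylum_layout <- function() {
  list(BamA = c("Proteobacteria", "Cyanobacteria", "Bacteroidetes",
                "Thermotogae"),
       BamA_cyano = "Cyanobacteria",
       TamA = "Proteobacteria",
       BamA_like = c("Proteobacteria", "Cyanobacteria"),
       Lipo = "Bacteroidetes",
       WD40 = c("Cyanobacteria", "Bacteroidetes"),
       Patatin = "Proteobacteria",
       Metallo = "Bacteroidetes",
       noNterm = c("Thermotogae", "Proteobacteria"),
       FhaC = "Proteobacteria",
       Hmw1B = c("Cyanobacteria", "Proteobacteria"),
       FtsQ_outgroup = c("Proteobacteria", "Cyanobacteria", "Bacteroidetes",
                         "Thermotogae"))
}

default_taxa <- function() {
  phyla <- c("Proteobacteria", "Cyanobacteria", "Bacteroidetes",
             "Thermotogae")
  rows <- lapply(phyla, function(p) {
    data.frame(taxon_id = sprintf("%s_t%02d", substr(p, 1, 4), 1:5),
               name = sprintf("%s sp. %d", p, 1:5), phylum = p,
               complete_proteome = c(TRUE, TRUE, TRUE, TRUE, FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset
#'
#' Samples sequences for every configured subfamily template and contaminant
#' family, assigns taxa according to the phylum layout, emits seed alignments
#' for the two barrel profiles and the POTRA profile (base consensus plus the
#' subfamily signature variants, ungapped), and produces ground-truth and
#' annotation tables.  Fully deterministic given the configuration.
#'
#' @param config A [generator_config()].
#' @param outdir Optional directory; when given, writes `sequences.fasta`,
#'   `truth.tsv`, `taxa.tsv`, `annotations.tsv` and `seeds/*.afa` there.
#' @return List: `records`, `truth`, `taxa`, `annotations` (data frames),
#'   `seeds` (named list of aligned seed sequence sets), `library`, `config`,
#'   and `paths` when `outdir` was given.
#' @export
generate_dataset <- function(config = generator_config(), outdir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  library <- make_domain_library(config$seed)
  templates <- architecture_templates()
  layout <- default_phylum_layout()
  taxa <- default_taxa()
  recs <- list()
  truths <- list()
  labels <- list()

  sample_family <- function(tmpl, n, label, allowed_phyla) {
    pool <- taxa$taxon_id[taxa$phylum %in% allowed_phyla]
    # round-robin first so every allowed taxon is covered when n >= |pool|
    tax <- if (n >= length(pool))
      c(rep(pool, length.out = length(pool)),
        sample(pool, n - length(pool), replace = TRUE))
    else sample(pool, n, replace = TRUE)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", tmpl$name, i)
      draw <- sample_sequence(tmpl, library, config$divergence,
                              config$indel_rate, id = id,
                              taxon_id = tax[i])
      recs[[length(recs) + 1L]] <<- draw$record
      truths[[length(truths) + 1L]] <<- draw$truth
      labels[[length(labels) + 1L]] <<-
        data.frame(id = id, label = label, stringsAsFactors = FALSE)
    }
  }

  with_seed(derive_seed(config$seed, "dataset"), {
    for (nm in names(config$templates)) {
      tmpl <- as.list(templates[templates$name == nm, ])
      sample_family(tmpl, config$templates[[nm]], "omp85_like", layout[[nm]])
    }
    if (config$n_contaminants > 0 && config$n_contaminant_families > 0) {
      per <- rep(config$n_contaminants %/% config$n_contaminant_families,
                 config$n_contaminant_families)
      extra <- config$n_contaminants %% config$n_contaminant_families
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      for (k in seq_len(config$n_contaminant_families)) {
        tmpl <- contaminant_template(k, library)
        sample_family(tmpl, per[k], paste0("contaminant:", tmpl$name),
                      unique(taxa$phylum))
      }
    }
    if (config$n_ftsq > 0) {
      tmpl <- as.list(templates[templates$name == "FtsQ_outgroup", ])
      sample_family(tmpl, config$n_ftsq, "outgroup",
                    layout$FtsQ_outgroup)
    }
  })

  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  annotations <- do.call(rbind, labels)
  # mask a fraction of the confident labels as unknown
  annotations$label_true <- annotations$label
  if (config$unknown_fraction > 0) {
    with_seed(derive_seed(config$seed, "unknowns"), {
      mask <- stats::runif(nrow(annotations)) < config$unknown_fraction
      annotations$label[mask & annotations$label != "outgroup"] <- "unknown"
    })
  }

  seeds <- build_seed_alignments(config, library, templates)

  out <- list(records = records, truth = truth, taxa = taxa,
              annotations = annotations, seeds = seeds, library = library,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "seeds"), showWarnings = FALSE)
    paths <- list(
      sequences = file.path(outdir, "sequences.fasta"),
      truth = file.path(outdir, "truth.tsv"),
      taxa = file.path(outdir, "taxa.tsv"),
      annotations = file.path(outdir, "annotations.tsv"))
    write_fasta(records, paths$sequences)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_taxa(taxa, paths$taxa)
    utils::write.table(annotations[, c("id", "label")], paths$annotations,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(seeds)) {
      p <- file.path(outdir, "seeds", paste0(nm, ".afa"))
      write_fasta(data.frame(id = names(seeds[[nm]]),
                             residues = unname(seeds[[nm]]),
                             stringsAsFactors = FALSE), p)
      paths[[paste0("seed_", nm)]] <- p
    }
    out$paths <- paths
  }
  out
}

# Seed alignments: base consensus plus the subfamily signature variants
# present in the configuration (ungapped, equal length by construction).
build_seed_alignments <- function(config, library, templates) {
  used <- templates[templates$name %in% names(config$templates), ,
                    drop = FALSE]
  omp_fams <- used$name[used$barrel_class == "omp85"]
  tps_fams <- used$name[used$barrel_class == "tpsb"]
  potra_fams <- used$name[used$potra_count > 0]
  if (config$n_ftsq > 0) potra_fams <- c(potra_fams, "FtsQ_outgroup")

  omp <- c(base = library$barrel_omp85,
           vapply(omp_fams, function(f)
             signature_variant(library, f, "barrel", library$barrel_omp85,
                               BARREL_SIGNATURE_DIVERGENCE), character(1)))
  tps <- c(base = library$barrel_tpsb,
           vapply(tps_fams, function(f)
             signature_variant(library, f, "barrel", library$barrel_tpsb,
                               BARREL_SIGNATURE_DIVERGENCE), character(1)))
  # pad the tpsb seed with mild jitters of the family variants so the
  # profile has more than two sequences even with a single tpsb family
  with_seed(derive_seed(attr(library, "seed"), "tpsb_jitter"), {
    k <- 1L
    while (length(tps) < 4L) {
      src <- tps[[1 + (k %% length(tps))]]
      tps[[paste0("jitter", k)]] <-
        paste(mutate_chars(strsplit(src, "", fixed = TRUE)[[1]], 0.05),
              collapse = "")
      k <- k + 1L
    }
  })
  pot <- c(base = library$potra,
           vapply(potra_fams, function(f)
             signature_variant(library, f, "potra", library$potra,
                               POTRA_SIGNATURE_DIVERGENCE), character(1)))
  list(omp85 = omp, tpsb = tps, potra = pot)
}
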