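---
title: "Classifying an outer-membrane protein superfamily: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying an outer-membrane protein superfamily: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ompfam` classifies members of the Omp85/TpsB outer-membrane protein
superfamily into subfamilies from sequence alone. This vignette explains the
statistical machinery behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where more than one reasonable choice existed.

## The classification procedure

The superfamily is defined by a conserved, membrane-embedded β-barrel; its
subfamilies differ in barrel sequence signatures and in N-terminal domain
architecture (POTRA repeat counts, accessory domains, lipoprotein anchors).
The pipeline turns that biology into a fixed stage order:

search (two barrel profiles) → merge by higher score → collapse identical
sequences → all-vs-all alignment → Markov clustering at inflation 1.5 →
contaminant label propagation → 250-aa length filter → re-cluster at
inflation 1.3 → envelope-based barrel/N-terminus partition → POTRA scan and
per-cluster consensus → lipobox detection → region similarity networks →
taxonomic distribution matrices.

### Profile search

A profile is a position-specific scoring matrix over the 20 amino acids,
built from an ungapped seed alignment. Columns with at least 50% residue
occupancy become match columns; emissions are log-odds in bits,

$$s_k(r) = \log_2 \frac{(c_{k,r} + w\,p_r)/(n_k + w)}{p_r},$$

with pseudocount mass $w = 5$ (enough to keep unseen residues from being
punished too hard in small seeds while preserving seed information) and
background $p$ set to the Robinson–Robinson natural composition. Targets are
scored by a local affine-gap dynamic program over profile columns (gap open
−4 bits, extend −1 bit; the X wildcard scores 0 everywhere); the *envelope*
is the target span of the optimal alignment. Score statistics come from
maximum-likelihood Gumbel fits to the scores of 300 background-random
sequences of length 350 (a typical barrel length):
$E = N\,(1 - \exp(-e^{-\lambda (S - \mu)}))$ with $N$ the number of target
sequences.

This is a deliberate simplification of a full profile HMM with forward-sum
statistics: it preserves the three quantities the pipeline consumes — bit
score, E-value, envelope — in an oracle-testable form. The envelope here is
the optimal-alignment span, not a posterior-probability envelope; with
per-site divergence in the data, envelope starts can be trimmed by a few
residues relative to the true domain boundary (they are exact at zero
divergence, which the tests verify).

Inclusion thresholds default to 1.0 (Omp85-type profile) and 0.1 (TpsB-type);
candidate retrieval additionally keeps everything up to a *reporting
threshold* of 10, because divergent true members — and, intentionally,
borderline contaminants — sit below the inclusion cutoffs. The exact value a
curator would use is not derivable from first principles; it is exposed as
`report_evalue` in `pipeline_config()`.

### Pairwise alignment and graph construction

All-vs-all similarity uses Smith–Waterman with BLOSUM62 and affine gaps
(open 11, extend 1; a gap of length $k$ costs $11 + (k-1)$). E-values follow
the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with the published gapped
constants ($\lambda = 0.267$, $K = 0.041$) taken as configurable inputs, not
estimated — deterministic E-values matter more here than composition-adjusted
accuracy. Identity is matches divided by all alignment columns, gaps
included (the stricter convention). Tie-breaks are fixed (end cell: first
maximum in row-major order; traceback: diagonal > up > left) so every result
is reproducible to the byte.

Graph edges connect pairs with $E \le 10^{-2}$, weighted
$\min(200, -\log_{10} E)$. The cap bounds the dynamic range so that a single
near-duplicate pair cannot dominate a cluster; the specific transform stands
in for the weight scheme of the original clustering tool chain, whose exact
semantics are not documented.

### Markov clustering

MCL is implemented natively: add self-loops (weight 1), column-normalize,
then iterate expansion (matrix square), inflation (entrywise power $r$,
re-normalize), and pruning (entries $< 10^{-5}$) until the largest entry
change falls below $10^{-9}$ or 100 iterations. In the limit, nodes with
positive diagonal are attractors; each attractor row's support is a cluster;
attractor rows with overlapping support form one cluster; a node claimed by
several clusters is assigned to the one whose smallest attractor index is
least (canonical MCL allows overlaps; downstream curation needs a
partition). Isolated nodes become singletons. Inflation 1.5 (curation pass)
and 1.3 (final pass) are the study's fixed granularity settings.

### Curation

Contaminant handling mirrors manual database curation as a mechanical rule:
labels (`omp85_like`, `contaminant:<family>`, `unknown`) propagate over whole
clusters. A cluster with only contaminant and unknown labels is discarded
entirely; one with superfamily labels and unknowns is kept entirely; a
cluster of pure unknowns is kept (its members were retrieved by the profile
search); a cluster mixing confident contaminant and superfamily labels is
flagged ambiguous and discarded with a warning — conservative by design,
never silently kept. The trade-off is real: when a lone borderline
contaminant lands inside a true subfamily's cluster (its family-mates having
fallen below the reporting threshold), the rule sacrifices that cluster.
This occurs at some generator seeds and is the documented cost of
conservatism. The length filter (strictly less than 250 aa) runs after
propagation; the curated set is then re-clustered.

### Domains, POTRAs, lipoboxes

The barrel runs from the best merged hit's envelope start to the sequence
end; the prefix is the N-terminus, reported only at ≥ 20 aa (shorter
N-termini leave the sequence in barrel analyses only). POTRA repeats are
found by iterated profile scanning: best local hit, record envelope, mask
with X, repeat while the per-sequence E-value (database size 1) stays at or
below $10^{-3}$; envelopes outside 25–125 aa are dropped, survivors numbered
P1..Pk from the N-terminus. Per final cluster, the modal repeat count $k^*$
is enforced: sequences with more repeats keep their $k^*$ best-scoring ones
(renumbered), sequences with fewer keep what they have — extra repeats are
removed, missing ones never invented. A modal tie is broken toward the
larger count (keeps more signal). POTRA detection by profile scanning
replaces a secondary-structure-based route; the same length filter is kept.

The lipoprotein signal is an explicit rule rather than an external
predictor: motif `[LVI][ASTVIG][GAS]C` with the invariant cysteine at
positions 15–40 and mean Kyte–Doolittle hydropathy > 1.0 over the eight
preceding residues (the hydrophobic signal core). All three thresholds are
exposed in the configuration.

### Networks and distributions

Sequence-region networks (full-length, barrel, N-terminus) are built over
0.80-identity greedy centroids with edges at $E \le 10^{-5}$; following the
original protocol, the barrel and N-terminus networks reuse the full-length
centroid set rather than re-reducing each region. The POTRA network reduces
segments at 0.50 identity and connects them at $E \le 10^{-3}$ (POTRAs are
short, so equal-score matches give larger E-values). Self-loops are removed
everywhere. Greedy centroid clustering processes sequences by decreasing
length (ties by id) and joins the *first* centroid at or above the identity
threshold — the fast-mode behaviour of the reference tool, and deterministic.

Distribution summaries use complete proteomes only: presence is the
percentage of a phylum's complete genomes containing at least one member of
a subfamily; copy numbers are plain per-genome counts. A phylum without
complete genomes yields missing cells, not 0%.

## The synthetic superfamily generator

Real inputs would be a protein database and curated family profiles; the
generator replaces them with a world whose every fact is known.

* A seeded domain library fixes consensus sequences: Omp85-type barrel
  (380 aa), TpsB-type barrel (300 aa, ~47% identity to the Omp85 type),
  POTRA repeat (75 aa), WD40 (280 aa), patatin (230 aa), metalloprotease
  (150 aa), and a 20-aa lipoprotein signal ending in a lipobox over a
  strongly hydrophobic core.
* Ten subfamily templates assemble these parts (signal → accessory → POTRA
  repeats → barrel, joined by fixed 8-aa linkers): BamA (5 POTRAs), TamA (3),
  BamA-like (2), Lipo (3 + lipobox), WD40, Patatin (1 POTRA), Metallo,
  noNterm (barrel only), FhaC (TpsB barrel, 2 POTRAs), Hmw1B (Omp85-type
  barrel, 2 POTRAs — mirroring the observation that this
  two-partner-secretion group carries an Omp85-like barrel).
* **Subfamily signatures.** Each subfamily owns fixed variants of the shared
  consensi: barrels diverged at 0.60 per site from the class consensus,
  POTRAs at 0.43. Members are then sampled around their subfamily consensus
  at the configured per-site divergence (default 0.25). These two levels were
  calibrated once, at design time, so the generated superfamily reproduces
  the qualitative structure the method targets: every family retrievable by
  a single class profile (the seed alignments contain the subfamily
  variants, exactly as curated seed alignments span a family's diversity),
  cross-subfamily *pairwise* similarity in the twilight zone — mostly below
  the $10^{-2}$ graph cutoff, so the fixed inflation values resolve the
  subfamilies — while multi-POTRA N-termini still interconnect at
  $10^{-5}$. Weaker signatures make the families collapse under inflation
  1.3; stronger ones disconnect the N-terminus network.
* **Composition.** Residues are drawn from the Robinson–Robinson natural
  composition, not uniformly: the published Karlin–Altschul constants assume
  natural composition, and uniform sequences have a measurably fatter
  score tail that manufactures spurious network edges.
* **Contaminants** are unrelated 350-aa families carrying a ~60-residue
  segment at ~0.35 identity to the Omp85 barrel consensus — close enough
  that a permissive search recovers a fraction of them (they sit astride the
  reporting threshold by construction), wrong enough that clustering
  isolates them.
* **Constraints on mutation.** The four lipobox positions mutate only within
  their motif classes (the cysteine is invariant), reflecting functional
  constraint; without this, no detector could meet a high sensitivity target
  at 20% divergence, and real lipoproteins do conserve the motif. Indels are
  confined to linkers by default so ground-truth domain coordinates stay
  exact (`indels_in_domains = TRUE` lifts this for stress tests).
* **Taxa.** Four phyla × five taxa (four of five flagged complete). BamA is
  ubiquitous; the Lipo subfamily is confined to one phylum and seeded into
  every one of its taxa; the remaining families occupy one or two phyla.
  30% of annotation labels are masked to "unknown" so label propagation has
  real work to do.

What the generator does **not** emulate: real Pfam emission statistics,
within-family rate heterogeneity and phylogenetic correlation, sequence
fragments, multi-domain insertions, genome context, or database-scale
redundancy. Passing tests therefore show the pipeline's logic is correct
under controlled conditions — not that its thresholds are optimal for any
particular real database release.

## Numerical choices and degenerate inputs

* Alignment tie-breaks and the first-match greedy rule make every stage
  deterministic; the pipeline is byte-reproducible given a seed.
* Gumbel fitting solves the profile likelihood for $\lambda$ by bracketed
  root finding on centered scores (tolerance $10^{-12}$) and errors on
  degenerate (constant) score sets; calibration requires ≥ 200 random
  sequences.
* E-values of 0 are floored at $10^{-200}$ before the log-weight transform.
* A sequence pair with no positive-scoring alignment yields score 0 and NA
  coordinates; such pairs never pass an E-value cutoff.
* Duplicate-group representatives are the lexicographically smallest id (no
  convention was given; this one is total and stable).
* `collapse_identical` uses exact full-length string identity; fragment
  merging is out of scope.
* MCL columns that prune to zero mass are reset to their diagonal;
  non-convergence at 100 iterations returns the current interpretation with
  a warning.
* Problem sizes: the reference study is 10 × 30 + 50 sequences of length
  ~300–800, chosen so the complete pipeline (three all-vs-all passes, two
  MCL runs, four networks) finishes in a few minutes on one core while
  leaving every subfamily with enough members (30) for modal statistics.

## Known limitations

* The profile stage is a calibrated PSSM, not a profile HMM; scores of
  genuinely multi-domain targets are dominated by the single best region,
  and per-target multi-domain hit splitting is not attempted.
* Karlin–Altschul constants are fixed inputs; compositionally biased real
  sequences would need composition-based statistics the pipeline does not
  implement.
* The ambiguous-cluster rule can discard true members for the sake of
  conservatism (see Curation above).
* Subfamily labels on real data require a user-supplied annotation table;
  nothing in the package harvests database annotations.
* The similarity networks are exported as edge/node tables; layout and
  rendering are left to external viewers.
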