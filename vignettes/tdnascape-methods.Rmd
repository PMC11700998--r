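---
title: "Methods: comparative tDNA landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative tDNA landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnascape)
```

# Scope and model

`tdnascape` analyses annotated tRNA genes (tDNAs), not raw genomes: gene
detection itself (covariance-model scanning), multiple sequence alignment,
tree inference and RNA folding are upstream tools whose outputs this
package consumes. What the package owns is everything downstream of the
annotation: filtering, content statistics, interval-density cluster
calling, regulatory-element scans, intron catalogues, cloverleaf/
covariation structure analysis, duplication–loss reconciliation, and a
synthetic-data generator that makes all of it testable without external
assemblies.

All genomic coordinates inside the package are 0-based half-open with an
explicit strand. The tRNAscan-SE convention (1-based inclusive, minus
strand encoded as begin > end) exists only inside the reader/writer pair,
which is an exact involution; BED6 (0-based) and GFF3 (1-based) exports
describe identical intervals after the convention shift. Confining the
conversion to one file is what makes the off-by-one-prone parts of this
kind of pipeline testable by round trip.

# Parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| score cutoff | 95 | bit score | the eukaryotic high-confidence post-filter's default isotype-score cutoff; boundary inclusive (a 95.0 gene is kept, 94.5 is not) |
| cluster merge gap | 1000 | bp | "at least three tDNAs within 1 kb" read as BEDTools merge distance |
| min cluster size | 3 | genes | the density criterion's gene count |
| upstream windows | 50, 300 | nt | 50 nt is where the A/T-rich signal and the scanned motifs live; 300 nt gives the no-signal contrast |
| downstream window | 50 | nt | where Pol III terminators are expected |
| min poly(T) run | 4 | nt | the shortest run treated as a terminator signal |
| TATA motif set | `"TATA"` | — | see below |
| covariation φ | 1 | — | weight of the non-pairable penalty |
| conservation threshold | 0.8 | frequency | majority-base frequency for a "conserved" alignment column |
| intron outlier flag | 50 | bp | several-fold above typical tRNA intron lengths |

# Decisions where the design was open

**Uniqueness.** "Unique tDNA sequences" is implemented as exact string
identity on full sense-strand genomic gene sequences, uppercase, introns
included. This is the strictest reproducible reading; it is a pure
function of the annotation and genome, so duplicating every gene halves
the percentage exactly — the property the tests assert.

**Cluster distance semantics.** "Within 1 kb of each other" is measured as
the end-to-start gap between half-open intervals, with a running maximum
end so that an interval contained in a longer one cannot break a run —
exactly what `bedtools merge -d 1000` does. Strand is ignored when
merging. A start-to-start mode exists behind a flag for comparison.
Bookended genes (gap 0) always merge. Note that under gap semantics three
genes can chain across more than 1 kb end to end; the criterion bounds
consecutive gaps, not the envelope.

**Cluster composition.** `homogeneous` requires all member isotypes equal;
`alternating` requires exactly two isotypes with no adjacent repeat (so
Tyr–Tyr–Ser is `mixed`, matching a strict reading of "alternating");
classification uses isotypes, not anticodons, because cluster patterns are
described at isotype level.

**TATA detection.** The original analyses used a cis-regulatory database
query that cannot be reproduced offline or deterministically. The scan is
therefore a configurable motif list, defaulting to the literal 4-mer
`TATA`; `tata_motifs()` documents an extended variant set. Overlapping
occurrences count separately (distinct start positions) — the simplest
auditable convention. Counts are binned 0 / 1 / 2 / >2.

**CAA windows.** The −10 window is the 10 bases immediately adjacent to
the gene start, inclusive of position −1; an occurrence must start within
the window and fit inside it.

**Poly(T) roles.** The first maximal run of ≥ 4 T's downstream is the
terminator; every later qualifying run is a backup. Mean terminator length
is computed over terminator runs only. Runs touching a window edge are
flagged truncated rather than guessed beyond the window.

**A/B boxes.** The internal Pol III promoter boxes are placed by structural
landmark rather than by manual alignment extraction: the A box is the
12-nt window starting at mature position 8 (1-based), the B box the 11-nt
window starting one base after the first T-stem 5′ position. The conserved
residues checked are T…GG (A box) and GG…CC (B box). Both anchors and
lengths are arguments, since box extraction was a manual step originally.

**Covariation statistic.** The score for reference pair (i, j) over N
aligned sequences is `B − φ·q`: q is the fraction of sequences whose two
bases cannot form a Watson–Crick or GT wobble pair (gaps never pair), and
B is the sum over unordered pairable sequence pairs of the Hamming
distance between their base-pair tuples, divided by C(N, 2). The score
lies in [−φ, 2]: 0 for a perfectly conserved pair, 2 for a fully
compensatory two-sequence case, negative when pairing is being lost. Only
the sign is interpreted (positive = compensatory); `zero` is assigned
below 1e-12 absolute. The formula is stated explicitly here because the
rendering tool originally used for these analyses does not publish one.

**Cloverleaf partitioning.** Helices are maximal stacked runs of pairs
((i, j) followed by (i+1, j−1)); bulges are rejected rather than patched,
because tRNA stems are canonically contiguous and a structure that does
not yield exactly four helices should fail loudly, not be guessed. Stems
are assigned in 5′ order: acceptor, D, anticodon, T; the variable loop is
the region between the anticodon-stem 3′ strand and the T-stem 5′ strand.
Stem lengths are reported in base pairs.

**Reconciliation conventions.** Only parsimony duplication–loss counting
under LCA mapping is implemented; tree rearrangement and bootstrap-aware
modes are out of scope, and non-binary trees are rejected rather than
resolved. Losses on the gene-tree edge u→v with species-path edge count d
are `max(d − 1, 0)` when u is a speciation and `d` when u is a
duplication; this is the standard LCA parsimony count (loss counting at
the root edge differs between tools and versions, so the convention is
documented rather than matched to any one program). The default leaf map
takes the species name as the leaf-label prefix up to the first
underscore.

**Regression.** Plain OLS of gene count on genome size in Mb via `lm`,
with R² = (Pearson r)² and the two-sided slope t-test (n − 2 df) as
p-value. Groups with fewer than three genomes are skipped with a warning;
a zero-variance response returns slope 0 and R² 0 by convention. No
phylogenetic correction is applied, deliberately.

# The synthetic generator

The generator is the package's study condition, not a tuning knob. It
emulates:

* canonical cloverleaf genes from one fixed 72-nt backbone per isotype
  (stems 7/4/5/5 bp, variable loop 4 nt, anticodon at mature 34–36),
  deterministic per isotype so ground truth stays computable; per-copy
  variation comes only from the `mutate_copies` substitution knob;
* introns at the canonical position after mature base 37, length 0 or
  8–200 bp (below 8 bp is rejected as biologically implausible), starting
  GCT and ending GAGT — the residues conserved in plant eMet tRNA introns
  — with a seeded random interior;
* upstream TATA/CAA motifs and downstream poly(T) runs at declared
  offsets; tandem and alternating gene groups with declared spacers; genes
  on both strands (minus-strand cassettes are reverse-complemented into
  the contig);
* i.i.d. background from configurable base frequencies (default 30% A/T,
  20% G/C, the A/T-rich side typical of plant nuclear genomes).

Within each gene's declared upstream-50 and downstream-50 windows the
background is sanitized: accidental TATA/CAA occurrences and T-runs ≥ 4
that touch any non-planted position are destroyed by a G substitution (G
appears in none of the scanned motifs, so sanitation converges). Expected
counts are then recorded by scanning the assembled sense-strand windows at
construction time — before placement, strand flipping and genome
assembly — so the recovery test exercises the full coordinate and strand
path of the pipeline rather than comparing a scanner with itself.
Cassettes are placed with at least merge-gap + 100 bp of clearance, so the
only clusters in a synthetic genome are the planted ones, and expected
clusters follow from the layout alone.

What the generator does *not* emulate: genome evolution, transposons,
isochores, pseudogenes with decayed structure, organellar genomes, or
motif position preferences beyond the declared offsets. Passing the
planted-truth tests therefore demonstrates that the pipeline measures what
is in a genome correctly; it does not validate biological conclusions
about real genomes.

Cohorts (`synthesize_cohort()`) draw gene counts as
`round(intercept + slope · size_Mb + N(0, sd))`, floored at 1, over evenly
spaced sizes. Defaults (69 genomes, 120–4800 Mb, slope 0.28 genes/Mb,
intercept 150, sd 160, eudicot/monocot/ANA labels) mirror an
angiosperm-scale survey: counts spanning roughly 150–1500 and a moderate
overall size correlation. Counts are drawn before any annotation, so the
cheap `annotate = FALSE` mode (metadata and counts only, used for
regression-scale simulations) yields bit-identical counts to the full
mode. `realize = TRUE` additionally writes contig background and is meant
for small sizes; the declared `size_bp` equals the summed contig lengths
whenever contigs exist.

# Numerical and degenerate-input choices

* Score filtering is boundary-inclusive (`score >= cutoff`).
* Composition profiles exclude truncated windows; information content is
  2 − Shannon entropy (log2) with no small-sample correction. In
  alignment-column statistics, gaps are excluded from the entropy but
  count in the majority-frequency denominator, and reduce the reported
  support.
* Empty genomes yield `NA` uniqueness, all-zero tally rows, and empty
  cluster sets; a nonempty cluster set with a zero gene total is an
  inconsistency error.
* All randomness flows through explicit seeds via a save/restore wrapper,
  so library calls never perturb user RNG state; equal seeds give
  byte-identical outputs.

# Problem sizes in the shipped tests

The suite validates, among others: cluster calls against a brute-force
transitive-closure oracle on 1,000 random layouts of up to 200 genes;
planted-truth recovery on 20 seeded ~200-kb genomes of 30–80 genes each;
strand-mirror invariance of every per-gene report; duplication minimality
against an exhaustive event-assignment enumerator on all gene/species
topology pairs up to 4 gene leaves over 2–3 species plus seeded random
5–6-leaf instances; covariation bounds on 10,000 random alignments; and
OLS slope recovery within the 99% confidence interval across 100 seeded
cohort replicates of 200 genomes. These sizes were chosen as the smallest
that exercise each property convincingly.

# Known limitations

* The TATA motif list is an approximation of a database-driven search; the
  default single 4-mer undercounts relative to a permissive variant set.
* Uniqueness and shared-sequence analysis use exact string identity; a
  single substitution separates sequences (near-identity search is out of
  scope, as is the alignment step it would require).
* Reconciliation assumes rooted binary trees and ignores branch lengths;
  no transfer events, no rearrangement of weakly supported nodes.
* Cluster calling bounds consecutive gaps, not cluster density over the
  envelope; very long chains can have overall density below 3/kb.
* The flank scanner does not mask neighbouring genes: windows may overlap
  adjacent features, as in the original protocol.
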