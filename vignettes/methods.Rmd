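---
title: "Codon-position GC, DSB hotspot motifs, and how GCxMotif computes them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-position GC, DSB hotspot motifs, and how GCxMotif computes them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GCxMotif)
```

## The model

Monocot genomes such as maize hold two gene populations separated by GC
content.  The separation is clearest per codon position: GC~1~, GC~2~ and
GC~3~ are the GC fractions over the first, second and third positions of
all codons of a gene, and the high class (peak around 0.90–0.95) is most
populous at the wobble position GC~3~, least at GC~2~.  Because meiotic
double-strand-break (DSB) hotspots in maize genes are built on a GC-rich
degenerate 19-mer (`GVSGRSGNSGRSGVSGRSG`) with a near-invariant G every
third base, the package quantifies three relationships: where motif
instances fall within gene structure, how their 3-nt GC periodicity maps
into the codon frame of the host gene, and whether motif-containing genes
are enriched in the high-GC~x~ and meiotic-expression classes.

The inferential machinery is deliberately plain: two-cell goodness-of-fit
chi-squares against genome-wide proportions (df = 1, two-sided, no
continuity correction) and two-sample t tests gated by an F test for equal
variances.  All expected counts enter the chi-square at full double
precision.  This matters: for the high-GC~3~ row of the motif-gene
enrichment table, the full-precision expectation (78.45 of 544) gives
p ≈ 1.9×10⁻⁷³ while the rounded expectation 78 gives ≈ 3×10⁻⁷⁴ — half an
order of magnitude from rounding alone.  `gofChisq()` therefore always
recomputes expectations from the universe counts.

## Coding sequences and phase

GC~x~ is computed on the sequence that contributes to the protein.  From a
GFF3 annotation the package keeps one representative transcript per gene —
the one with the longest total CDS, ties broken by the lexicographically
smallest transcript ID.  This rule is a deterministic stand-in for
upstream "filtered gene set" annotations that already carry one model per
locus; when an input has isoforms, the rule decides reproducibly.  Within
the chosen transcript, overlapping CDS intervals are merged (tolerated,
though invalid GFF3) so no genomic base can be counted twice.

The CDS *phase* — the number of bases to remove from a segment's start to
reach the first base of a complete codon — is read from GFF3 column 8, or
inferred from segment lengths (first segment phase 0) when absent.  The
spliced coding sequence of a minus-strand gene is the concatenation of
reverse-complemented segments in transcription order.  Codon framing drops
the first `phase_offset` bases; a trailing partial codon contributes its
present positions by default (`drop_partial = TRUE` discards it instead —
both behaviours are exact, the default maximises data use, and on genes of
hundreds of codons the difference is far below the 80% classification
cutoff's resolution).

Undefined values propagate as `NA`, never as 0: a gene whose CDS is all
ambiguity codes has no GC~x~ and silently entering a 0 into a density or a
class tally would bias both.

## GC classification and densities

A gene is high-GC~x~ when gc~x~ ≥ 0.80 — the cutoff is inclusive, so a
gene at exactly 0.80 is in the high class.  Classification is monotone in
the cutoff by construction.  Density curves use a Gaussian KDE with
Scott's bandwidth rule (`stats::bw.nrd`), renormalised to integrate to 1
over the evaluated support; the bandwidth is overridable because no single
rule suits both the sharp high peak and the broad low peak at every sample
size.

The degeneracy profile of the standard genetic code (how many of the 64
codons tolerate a synonymous substitution at each position) contextualises
the wobble hypothesis: position 3 dominates (61 codons), positions 1 and 2
trail far behind (8 and 2).  Stop codons are treated as their own amino
acid class, so stop-to-stop changes count as synonymous; this convention
only affects three codons and is stated here because other conventions
exist.

## Motif model and scanning

The original hotspot position weight matrix was estimated from ~900
ChIP-defined hotspot regions and is not available; the package
reconstructs a PWM from the IUPAC consensus.  Each position's probability
mass is uniform over the bases its code allows (`V` → A/C/G at 1/3 each,
`S` → C/G at 1/2, `N` → 1/4 each); disallowed bases receive a
pseudo-probability ε = 10⁻³ and the column is renormalised.  The ε keeps a
single mismatch penalised but finite, so the stringency threshold remains
a meaningful dial rather than a cliff.  Scores are log₂ odds against a
uniform background (overridable).  Since within-code probabilities are
uniform, every allowed base attains the column maximum: the consensus
describes a *set* of maximal words (the all-G 19-mer among them), which is
the correct reading of a degenerate consensus.

A window is a hit when its score reaches `stringency × maxScore`, default
0.80.  The alternative convention anchored to the score *range*
(`minScore + 0.80 × (maxScore − minScore)`) is available via
`scoring = "minmax"`; which convention the original hotspot scan used is
not recoverable, and the max-anchored form is the stricter and simpler
default.  Both strands are scanned by default (the analysis upstream is
silent on strand; hits carry their strand so either convention can be
tabulated), overlapping hits are all retained — per-gene counts up to 16
imply dense tandem occurrences that greedy masking would destroy — and an
`N` in a window contributes the background-weighted mean of its column's
scores, i.e. the expected score of a background base, neither reward nor
catastrophic penalty.

A hit's *region* (CDS, intron, UTR) is decided by its leftmost genomic
base.  Its codon frame is defined only when all 19 bases are consecutive
in the spliced coding sequence — in practice, inside a single CDS segment;
a hit straddling a splice junction keeps region CDS but no frame, because
frames are meaningless across an intron.  For a frame-defined hit at
0-based coding-sequence offset *c* in a gene with phase offset *φ*, the
frame is ((c − φ) mod 3) + 1: frame 1 means the motif's first base is a
codon's first base.

## Periodicity and variance-gated comparisons

Per-position GC across hits is partitioned into the fixed periodicity
groups {1,4,…,19}, {2,5,…,17}, {3,6,…,18} (sizes 7/6/6), framed on the
motif, not the codon.  Mapping motif bases into *codon* positions instead
uses the hit's frame, and trims end overhangs: bases of a first codon
whose position 1 the motif does not cover, and of a last codon whose
position 3 it does not cover, are dropped so only complete codon columns
are compared.

Group comparisons use the spreadsheet-style two-stage test: a two-sided F
test for equal variances routes to a pooled (homoscedastic) t test when
not rejected, a Welch (heteroscedastic) t test when rejected.  The gate
level defaults to α = 0.10.  This is the only level consistent with the
reference analysis this package mirrors, where F p-values of 0.058 and
0.063 were routed to the heteroscedastic column (ruling out α = 0.05) and
0.289–0.596 to the homoscedastic one.  The unit of observation for these
tests is the per-position GC value (samples of size 7, 6, 6), matching the
grouping above; no multiple-testing correction is applied across the three
pairwise comparisons, mirroring the reference analysis.

Degenerate inputs are defined explicitly: two zero-variance samples with
equal means give t = 0, p = 1 under the pooled kind (the F test is
undefined there and equal variances is the only sensible reading).

## Enrichment tests

All contingency analyses reduce to `gofChisq(observed_yes, observed_no,
universe_yes, universe_no)`.  The class co-occurrence analysis conditions
on each high class in turn and tests each other class's membership within
it against genome-wide proportions; the expected overlap of two classes
under random sampling is n~a~·n~b~/N.  Expression labels (up/down per
comparison tissue) are consumed as input — the package never calls
differential expression — and tested two ways: label rates within the
motif-containing genes against genome-wide label fractions, and high/low
GC~x~ splits within each expression class against genome-wide GC~x~
proportions.  Genes absent from the gene universe are excluded with a
message; conditioning or universe classes that are empty are skipped with
a warning rather than producing a zero expected cell.

p-values are reported at full double precision; below 10⁻³⁰⁰ the display
floors at "< 1e-300" (the underlying value underflows to 0 and is reported
as such in machine-readable output).

## The synthetic-data generator

The simulator exists so every stage can be tested against planted truth.
Its defaults *are* the study conditions the package mirrors:

* class proportions 3647/629/5719 high (of 39,656) and the rest low;
* per-codon-position GC probabilities: 0.90 at the designated position of
  a high-class gene, 0.45 elsewhere; low-class genes 0.50/0.45/0.50
  (positions 1/2/3) — placing the low peaks near 50% for GC~1~/GC~3~ and
  45% for GC~2~, and the high peak at 90%;
* introns and UTRs at GC 0.40, intergenic spacers at 0.35 — non-coding
  sequence is the lower-GC matrix the genic peaks sit in;
* gene sizes 100–400 codons over 1–4 exons, intron lengths 60–180 nt, UTRs
  30–120 nt: compact but structurally complete gene models;
* motif plantings: carrier genes drawn with odds 5 toward high-GC~x~
  classes over a 5% baseline, per-gene counts truncated-geometric on 1..16
  (mean ≈ 4, matching a per-gene histogram that ranges to 16), frames at
  the observed genic split 0.369/0.165/0.466, instances sampled from the
  PWM and accepted at the scan stringency;
* expression labels at the genome-wide class fractions per comparison
  tissue, with odds 0.3 of up-regulation for motif genes and 0.4/2.5
  for high-GC~x~ genes being up/down — the direction structure the
  enrichment tables are built to detect.

Codons are sampled independently per position rather than from a real
codon-usage table: the downstream analysis consumes only positional GC,
and independence makes every truth value analytic.  Stop codons are
rejected in the CDS body and one is appended per gene.  CDS segments are
split at arbitrary base boundaries so nonzero internal phases are
exercised, but every gene starts at a codon boundary (phase offset 0);
nonzero *leading* phase is covered by hand-built fixtures in the tests
rather than the generator.  One gene per locus; the representative-
transcript rule is exercised by dedicated multi-isoform fixtures.

What the simulator does *not* emulate: real codon usage and amino-acid
composition, GC gradients along genes, transposable elements, nested or
overlapping genes, alternative splicing, and any evolutionary dynamics.
Passing recovery tests therefore shows the pipeline measures what was
planted under clean conditions — not that a real genome's annotation
quirks are all handled, which is what the hand-built edge-case fixtures
are for.

## Problem sizes and determinism

Tests and the acceptance script run simulations of 300–800 genes
(contigs of ~25 genes), oracle-equivalence sweeps of 500 random sequences
for the scanner and 1,000 for codon-position GC, and null-calibration
loops of 60–200 replicates.  These sizes give stable recovery statistics
(binomial 99% intervals at n = 500 resolve the planted 9.2/1.6/14.4%
proportions) while keeping a full run in minutes.  Every stochastic step
is a deterministic function of an integer seed: the simulation config
requires one, and re-running any stage with the same config is
byte-identical.

## Known limitations

* The PWM is consensus-derived, not data-derived; information content per
  position is flattened within each IUPAC code.  Conclusions about score
  *margins* (how far above threshold hits sit) should not be over-read.
* Genome-scale reference counts shipped with the package document the
  maize B73 (RefGen_v2, set 5b) analysis and are used to verify
  arithmetic and statistics; reproducing them from sequence requires that
  reference genome and is out of scope.
* A hit overlapping two genes is reported once per gene and flagged
  `multi_gene`; downstream per-gene counts treat each assignment
  independently, which double-counts such hits if both genes are kept.
* The chi-square is asymptotic; with expected cells below ~5 (tiny
  simulated GC~2~ classes) the package still reports the statistic, and
  the caller should prefer exact tests at such sizes.
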