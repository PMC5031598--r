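# GCxMotif

Codon-position GC content and double-strand-break hotspot motif enrichment
in plant genomes.

## The problem

Maize and other grasses carry two distinct populations of genes separated
by GC content — a *bimodal* distribution that is sharpest at individual
codon positions.  Writing GC<sub>1</sub>, GC<sub>2</sub> and GC<sub>3</sub>
for the GC fraction over the first, second and third (wobble) positions of
all codons in a gene (collectively GC<sub>x</sub>), the high class peaks
near 90–95% GC and the low class near 50–55%.  Meiotic recombination is a
candidate driver: double-strand-break (DSB) hotspots in maize genes sit on
a GC-rich degenerate 19-mer, `GVSGRSGNSGRSGVSGRSG`, whose every third base
is nearly always G — a 3-nt periodicity reminiscent of the codon itself.

GCxMotif packages the analysis that connects the two observations, for
anyone who has a genome (FASTA), an annotation with CDS phases (GFF3), and
optionally differential-expression gene lists:

* phase-aware spliced coding sequences and per-gene GC, GC<sub>1..3</sub>;
* high/low GC<sub>x</sub> classification at an inclusive 80% cutoff;
* PWM scanning for the hotspot consensus at a fractional-score stringency
  (default 80% of the maximal score), on both strands, overlaps retained;
* codon-frame assignment of motif instances and per-frame / per-periodicity
  GC summaries with variance-gated (F-test then pooled/Welch) t tests;
* genome-proportion goodness-of-fit chi-squares for motif–class and
  expression–class enrichment, with expected counts carried at full
  precision;
* a synthetic genome simulator (FASTA + GFF3 + truth tables) so every stage
  is testable with planted ground truth and no downloads.

## The statistics at the core

For a gene subset of size *n* (say, the motif-containing genes) and a
genome-wide class split (*Y*, *N*), the expected membership is
*E* = *n·Y/(Y+N)* and the test statistic

> χ² = (O − E)²/E + ((n−O) − (n−E))²/(n−E),  df = 1, two-sided,

with no continuity correction.  Expected counts are never rounded before
the test: with vanishing p-values, testing against a rounded expectation
visibly distorts log₁₀(p).  The motif scanner scores windows with log₂
odds of a consensus-derived PWM (uniform probability over each IUPAC
code's allowed bases, pseudo-probability 10⁻³ elsewhere) against a uniform
background, accepting windows scoring ≥ 0.80 × max score.

## Worked example

Simulate a 120-gene genome with planted classes, motifs and expression
labels, then run the pipeline end to end:

```r
library(GCxMotif)
cfg <- simulationConfig(seed = 17, n_genes = 120)
sim <- simulateStudy(cfg)
dir <- tempfile("demo_")
writeSimulation(sim, dir)                      # FASTA + GFF3 + truth TSVs
res <- runPipeline(file.path(dir, "genome.fa"),
                   file.path(dir, "annotation.gff3"),
                   file.path(dir, "out"),
                   expression_labels = file.path(dir, "labels.tsv"))

classCounts(res$profile)
#>   gcx n_high n_low n_labeled
#> 1 GC1      9   111       120
#> 2 GC2      2   118       120
#> 3 GC3     20   100       120
```

The simulator drew gene classes at the genome-scale proportions (9.2% high
GC<sub>1</sub>, 1.6% high GC<sub>2</sub>, 14.4% high GC<sub>3</sub>) and
the recovered counts match the draw.  The scan found all planted motifs —
`res$per_gene$total_motifs` is 23 in 10 genes, 62.5% of them with more
than one instance — and the enrichment table shows the planted bias of
motifs toward high-GC<sub>3</sub> genes:

```r
subset(res$enrichment, condition == "GC3")
#>   condition observed_yes expected_yes observed_no expected_no chi2            p
#> 3       GC3            5     1.333333           3    6.666667 12.1 0.0005042182
```

The same machinery reproduces genome-scale reference arithmetic exactly.
High-GC<sub>1</sub> membership among the 544 motif-containing maize genes,
against the genome-wide split of 3,647 high / 36,009 low:

```r
gofChisq(130, 414, 3647, 36009)
#> Goodness-of-fit chi-square (two-sided, df = 1)
#>   observed: yes = 130, no = 414
#>   expected: 50.0295, 493.9705
#>   X-squared = 140.7772, p = 1.79998e-32

expectedOverlap(3647, 5719, 39656)   # high-GC1 x high-GC3 random overlap
#> $expected
#> [1] 525.953
#> $rounded
#> [1] 526
```

`runPipeline()` leaves TSV table analogues (class counts, motifs per gene,
periodicity-group t tests, enrichment chi-squares, expression cross-tabs),
BED6 + TSV motif hits, PDF density/scatter figures, a JSON summary and a
parameter log under its output directory.

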