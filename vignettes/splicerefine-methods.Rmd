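---
title: "Methods: evidence model, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence model, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicerefine)
```

# Scope and evidence model

`splicerefine` operates strictly downstream of read alignment. Its inputs
are alignment-level evidence: splice-junction records with per-sample
non-redundant read support, per-base coverage tracks, and per-gene read
counts. Nothing in the package touches FASTQ reads, mismatch counting or
spliced alignment itself; those belong to the aligner. This boundary also
shapes the synthetic-data generator, which emits evidence at the same level
rather than simulating sequencing.

The biological setting is a ciliate macronuclear genome: short introns,
highly A+T-rich noncoding sequence, and the ciliate nuclear genetic code
(NCBI table 6) in which TAA and TAG encode glutamine and TGA is the sole
stop. Every ORF and premature-stop computation in the package uses this
code; using the standard code here would be simply wrong, since almost
every ciliate CDS contains in-frame TAA/TAG codons.

## Coordinates

All internal coordinates are 1-based inclusive, the convention shared by R,
IRanges/GenomicRanges and GFF3. BED12 and bedGraph are 0-based half-open on
disk; rtracklayer performs those conversions at the I/O boundary, so the
conversion logic exists in exactly one place and round-trips are exact.

# Junction acceptance

A junction is accepted into the detection universe iff

* its terminal intron dinucleotides are GT…AG in transcript orientation
  (genomic CT…AC on the minus strand). Unstranded junctions get their
  strand inferred from the dinucleotides; junctions non-canonical in both
  orientations are dropped with a log line.
* at least `min_anchor = 8` bp aligned on both sides of the junction;
* intron length within `[10, 10000]` bp, the same bounds a spliced aligner
  would use for this genome;
* non-redundant support ≥ 1 (≥ 2 wherever the junction serves as evidence
  for an alternative-splicing call).

"Non-redundant" is defined as the number of distinct alignment spans
(start, end) over the junction. Deduplicating by position is robust to PCR
duplicates and is computable from alignment-level records; deduplicating by
read sequence would need the reads themselves, which are out of scope.

Filtering is idempotent and monotone in every threshold; both properties
are tested.

# Transcript assembly

The assembler is deliberately simple: maximal intervals of depth ≥
`min_cov = 2` become exonic islands, sub-threshold gaps ≤ `max_gap = 25` bp
are bridged (so dips inside an exon do not shatter it), and accepted
junctions whose two anchor bases both land in islands link islands into
connected components; each component is one transcript. Within a component
the exon chain is cut at a non-conflicting subset of junctions chosen
greedily by (support desc, leftmost, shortest) — a deterministic rule, so
the same input always yields the same chain. When two isoforms have equal
support the tie-break decides which chain becomes the "transcript"; the
alternative-splicing caller does not depend on that choice (see below).

These three thresholds are package choices, exposed in `run_pipeline()`'s
`params`; they are conservative enough that on clean synthetic data
split/fused calls are unambiguous.

# Model comparison statuses

Each annotated model gets exactly one status, resolved in this order:

1. **fused** — one transcript's exons overlap ≥ 2 models on a compatible
   strand: the models should be one gene. The corrected annotation merges
   them under the id `A+B`.
2. **split** — ≥ 2 assigned transcripts, separated by a zero-coverage run
   ≥ `zero_gap = 50` bp inside the model span: the model should be several
   genes (`id.1`, `id.2`, …). The zero-coverage requirement is what
   distinguishes a genuinely silent inter-gene gap from an expression dip.
3. otherwise the best-overlapping transcript's intron chain decides:
   identical chain → **complete_match**; same intron count with each intron
   overlapping its counterpart → **boundary_mismatch**; anything else →
   **missing_or_extra_intron**; no overlapping transcript → **undetected**.

A transcript is assigned to a model if it shares ≥ 1 bp of exonic overlap
on the same strand; intron-less transcripts are unstranded and may match
either strand. Ties among transcripts are broken by overlap, then leftmost
coordinate, then id — again fully deterministic.

Corrected models replace the intron chain with the transcript chain; UTRs
are added afterwards and only for `complete_match` models, by extending
through contiguous depth ≥ 1 until the first zero-depth base or the nearest
neighbouring gene span. This contiguity rule is the simplest one consistent
with coverage that tapers toward transcript ends; it will underestimate
UTRs wherever coverage happens to hit zero early, which is the conservative
direction.

Novel transcribed regions require a fully intergenic span ≥ 300 bp because
most UTRs are shorter than that: a lower threshold would mostly harvest UTR
fragments of truncated assemblies, not new genes.

# Alternative splicing

All calls use the stringent evidence rule: every junction involved needs
non-redundant support ≥ 2, and intron retention needs depth ≥ 10 at every
single base of the intron.

* **alt 5′ / alt 3′**: a pair of junctions sharing one splice site
  (strand-aware: shared acceptor with differing donors is alt 5′). If one
  junction matches an annotated intron it is reported as the reference; the
  classification itself is symmetric, so it does not matter which isoform
  the assembler happened to pick as the transcript chain.
* **cassette**: a skip junction whose endpoints coincide with the donor of
  intron *i* and the acceptor of intron *i + 1*, coexisting with both
  inclusion junctions. The skipped exon must be an annotated internal exon
  — of the corrected model or of the pre-correction model for that locus.
  Accepting the pre-correction exon matters in the equal-support corner
  case where the skip isoform won the assembly tie-break and the corrected
  model therefore lacks the exon. Inclusion of *novel* (unannotated) exons
  is intentionally out of scope.
* A junction pair that participates in a cassette triple is not also
  reported as alt 5′/alt 3′, and each event is emitted once per gene.
* **intron retention** requires evidence of *both* isoforms: full-depth
  coverage across the intron *and* spliced support ≥ 2 for the same intron.
  Without the spliced side, a fully covered "intron" is indistinguishable
  from a mispredicted intron in a constitutively unspliced gene — it is an
  annotation error, not alternative splicing, and the model-comparison
  stage is where it gets fixed.

Events are evaluated pooled (all samples) and per stage group — growth
(G-m), starvation (S-3, S-15), conjugation (C-2, C-8) — by summing support
and coverage within the group and re-applying the full criteria. An event
meeting the criteria in exactly one group is stage-specific. Grouping at
the stage rather than the sample level reflects that the two starvation and
two conjugation samples are time points of one physiological state.

Premature termination codons are scanned by walking codons of the
alternative isoform from the annotated CDS start; the flag is set iff an
in-frame TGA occurs strictly upstream of the annotated stop's position in
that isoform (or anywhere, if the annotated stop was removed by the event).

## Intron-retention specificity

Per gene, the retention count of an intron is the *minimum* per-base depth
over the intron — a conservative proxy for "reads indicating retention"
that never exceeds what the weakest base supports. A gene's specificity is
`max / sum` over its introns (ties reported at the 5′-most intron; the
value is unaffected). The binned summary table reports, per intron-count
bin, the mean specificity of the bin's IR genes, and the total row carries
the IR-gene-count-weighted average, rounded to 2 decimals. Note that a
count-weighted average generally differs (already in the second decimal)
from the unweighted mean of the bin values; this package always reports the
weighted form, as defined for `ir_weighted_average()`.

# Expression

RPKM is `1e9 · count / (exon_len · total)`, with the per-sample totals
taken as the column sums of the count table so that the denominators are
exactly the mapped reads accounted for. Stage-level RPKM is the arithmetic
mean over the stage's samples — the simplest aggregation consistent with
comparing physiological states, and exposed in the API for anyone who
prefers medians. A gene is stage-specifically up-regulated iff its stage
RPKM is > 5 (strict) and ≥ 5-fold the RPKM of *every* other stage
(dominance, so the three stage sets are disjoint by construction); a zero
denominator with a positive numerator counts as infinite fold.

Probe renormalization assigns each probe to the unique corrected gene whose
exon union contains the probe interval — probes in no gene or in two
overlapping genes are dropped with a log line — and takes the per-gene
median intensity per sample. Platform correlation uses Pearson r on log2
values, with RPKM offset by +1 before the log to keep zero-count genes
finite. GO enrichment is the hypergeometric upper tail
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`) with Bonferroni
multiplication by the number of terms that have ≥ 1 test-set gene (terms
untestable in the set are not counted against it), significant at corrected
p < 0.01.

# The synthetic-data generator

`generate_truth()` emulates the statistical structure the pipeline is built
for: noncoding A+T fraction 0.87 (coding 0.75); intron lengths
10 + Gamma(shape 2) with mean 135 bp, clamped to [10, 10000]; 2–7 exons per
gene; exponential UTRs (means 80/160 bp, capped at 290 bp so UTRs stay
below the novel-region threshold); ≥ 600 bp intergenic spacers so
fusion/novel calls are unambiguous; AS planting rates proportional to an
event spectrum dominated by intron retention (cassette 0.0056, alt5 0.0104,
alt3 0.0099, IR 0.0337 — about 6 % of genes, 13 % of events
stage-restricted and skewed to conjugation); per-gene log10 expression SD
1.0, spanning about six orders of magnitude across ±3 SD; and planted
annotation errors (fuse/split/boundary/missing-intron, 4 % each).

Observables are derived deterministically where the underlying computation
is deterministic — coverage is `depth × expression` over exonic bases,
scaled by the isoform fraction over event-specific regions; counts are
`coverage × transcribed_length / 100` — while junction support is
Poisson(`junction_read_factor × coverage × isoform fraction`), the simplest
count model that keeps stochastic acceptance behaviour testable. With the
default `depth = 40` and minor isoform fraction 0.5, a planted retained
intron sits at 20× in each sample (10× per stage group at the single-sample
growth group), exactly at the regime the IR threshold is meant to probe.

What the generator does **not** emulate — and what green tests therefore do
not demonstrate about real data: mappability and positional coverage bias,
PCR duplication structure, non-canonical splice sites, overlapping genes,
polyA-capture artifacts of non-coding transcripts, multi-isoform mixtures
beyond one planted event per gene, and noise in the annotation beyond the
four planted error classes. Recovery tests on this generator establish
correctness of the *logic*, not field performance.

## Problem sizes

The test suite and acceptance script run the generator at 30–80 genes on
2–5 scaffolds of 60–80 kb, with recovery checks at uniform expression
(log10 SD 0) and 40× depth so that every planted event is above threshold
by construction; the classifier-vs-oracle sweep uses 150–200 random toy
genes with ≤ 4 introns and ≤ 6 candidate junctions. These sizes exercise
every code path while keeping a full run in the order of a minute.

# Degenerate inputs and numerical conventions

* Zero depth everywhere: empty coverage, zero junction support, all models
  `undetected`, zero events — all handled, all tested.
* A sample with zero total counts contributes RPKM 0 rather than dividing
  by zero.
* `ir_specificity()` is undefined (error) at zero total retention reads;
  callers exclude such genes from summaries.
* Report rounding: percentages to 1 decimal, specificity frequencies to 2
  decimals, mean AS intron lengths to 2 decimals.
* All orderings (junction tables, GFF3 output, report files) are
  deterministic by (scaffold, start, id); identical configuration and seed
  give byte-identical output files.

# Known limitations

* The assembler picks a single chain per locus, so the corrected model of a
  genuinely alternatively spliced gene reflects whichever isoform had more
  support (ties broken deterministically); isoform-abundance deconvolution
  is out of scope.
* UTR inference requires `complete_match` status and therefore says nothing
  about corrected or undetected models.
* Cassette calls are limited to annotated internal exons; novel-exon
  inclusion is not reported.
* GO enrichment assumes the gene→term map is given; deriving GO annotations
  from sequence is out of scope.
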