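---
title: "Integrating chromatin accessibility, TF binding and expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chromatin accessibility, TF binding and expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmodes)
```

## The problem

A nuclear receptor such as LXR shapes the hepatic transcriptome in several
distinct ways at once: it can activate a target when its ligand arrives,
repress a target upon ligand binding, or be required for basal expression
while remaining blind to a pharmacological agonist.  Distinguishing these
regulatory modes needs three genome-wide measurements around one
perturbation — chromatin accessibility (ATAC-seq) in knockout versus
wild-type tissue, receptor binding (ChIP-seq) under basal and
agonist-stimulated conditions, and differential expression for the two
contrasts (knockout vs wild-type; agonist vs vehicle).  `regmodes`
implements the integration: ranked-bin motif-accessibility landscapes,
genomic-feature annotation of differential peaks, binding / expression /
accessibility cross-tabulation, cut-site footprinting, and a four-segment
classifier of direct target genes.

## The ranked-bin motif landscape

Peaks with fewer than `min_total_count` (default 10) raw counts summed over
all samples are removed.  Counts are normalised to RPKM,
`counts / (width_kb * lib_size / 1e6)`, with the library size taken from
sample metadata (total mapped reads) rather than recomputed from in-peak
counts, because peak counts cover only a fraction of the library.  Replicates
are averaged per condition, and peaks are ranked by the difference of the
condition means.  The signed ranking puts the largest loss first and the
largest gain last; an absolute-change ranking is available as
`mode = "absolute"`.  Ties break on the peak id in the C locale, making
every ordering reproducible.  Whether a study's published ranking used RPKM
or raw mean counts is often ambiguous; both are supported
(`value = "rpkm"` is the default and is what the RPKM-based large-loss flag
uses).

Ranked peaks are cut into `floor(n / bin_size)` contiguous bins (at least
one), sizes differing by at most one, remainder spread over the leading
bins — 73,597 peaks at bin size 1,000 give exactly 73 bins.  For each motif
and bin, enrichment is the one-sided hypergeometric upper tail for the
count of motif-bearing peaks in the bin, with all binned peaks as the
population.  This is the transparent, exactly testable choice; a GC- or
length-matched background is deliberately out of scope, so absolute
p-values should be read as descriptive landscape heights, not calibrated
genome-wide significance.  The heatmap matrix stores `-log10 p` raw;
Benjamini–Hochberg correction is applied only in ranked result tables
(`subsetEnrichment`).

Motifs are scanned by log2-odds against the motif's background base
frequencies, on both strands, with a hit threshold at
`pwm_score_fraction` (default 0.8) of the motif's maximum achievable
score.  This threshold is simple and monotone; it deliberately avoids
per-site p-value machinery.  `N` bases score `-Inf`, so windows containing
them never fire.

After the landscape is built, motifs that never reach `-log10 p >= 3` in
any bin ("nonenriched") or whose range across bins is below 1 ("not
changing") are dropped; the two thresholds are config keys
(`enrich_min`, `change_min`) because the corresponding published filters
are stated without numbers.  Motifs sharing a family label whose PWM
similarity exceeds 0.90 are merged by single-linkage closure, the merged
row being the per-bin best (elementwise maximum of `-log10 p`).
Similarity is the maximum Pearson correlation of aligned probability
columns over all ungapped offsets with at least four overlapping columns,
considering the reverse complement as well.  Two consequences are worth
knowing: the metric is permissive for short, consensus-like motifs (a
perfectly matching 4-column overlap scores 1), and single linkage can
chain motifs that are pairwise below threshold — both are properties of
the stated metric, and the member lists of every merged row are retained.

## Annotation and binding assignment

Each peak is classified at its midpoint with precedence
promoter > TTS > exon > intron > intergenic.  The promoter window is
−1,000/+100 bp around the TSS on the gene strand and the TTS window
±100 bp, matching common annotator defaults; both are configurable.
Classifying at the midpoint (rather than any-overlap) forces every peak
into exactly one class, which the tests verify as a partition.  The
nearest gene is the one with the TSS closest to the midpoint, ties going
to the lexicographically smaller gene id; the signed distance is negative
upstream on the gene strand.

Binding sites map to genes by the `"span"` rule: a site belongs to every
gene whose span extended by the promoter window contains the site
midpoint, falling back to the nearest TSS when none does.  The pure
nearest-TSS rule is available as `rule = "nearest"`.  The span rule is the
default because a site deep inside a long gene body otherwise gets
assigned to a neighbouring gene's closer TSS, which is rarely the intended
reading of "the gene's binding site".

## Footprinting

The footprint module is a deliberate simplification of HMM-based
footprinting tools: per-base cut counts are aggregated in a ±100 bp window
around motif occurrences, oriented by hit strand, normalised by the total
cuts in all aggregated windows (so a uniform track gives a flat profile at
`1/(2w+1)`), and summarised as a protection depth
`1 - mean(in-motif) / mean(flank)` with the flank being the outer 25 bp
per side.  The in-motif span is `±floor((len-1)/2)` around the center so
that every selected position lies inside the occupied span on either
strand, which makes the estimator unbiased on simulated dips.  Outputs are
comparable in kind (profiles, protection depths, condition differences) to
dedicated tools, not numerically.  No Tn5 +4/−5 offset correction is
applied because the simulator emits cut positions directly; real data
would need that correction applied upstream.

## The mode classifier

Genes are classified per contrast as down / up / unchanged by adjusted
p < `de_alpha` (default 0.05) and the sign of log2FC; no fold-change
magnitude gate is applied by default, matching the usual published
criterion.  The four canonical segments are the cross of the knockout and
agonist calls, gated on binding evidence:

| knockout | agonist   | bound | mode              |
|----------|-----------|-------|-------------------|
| down     | up        | yes   | ligand_activated  |
| up       | down      | yes   | ligand_repressed  |
| down     | unchanged | yes   | basal_required    |
| up       | unchanged | yes   | basal_repressed   |

DE genes without binding evidence are `indirect`; knockout-unchanged but
agonist-responsive bound genes are `agonist_only`; bound genes DE in the
same direction under both contrasts fall outside the four segments and are
labelled `other_direct` so that the modes still partition the gene
universe.  Agonist-condition binding-site sets are treated as a union with
the basal set (the basal set is a subset), and the evidence flag records
whether a gene's support is basal or agonist-only.

## What the simulator emulates — and what it does not

`simulateStudy()` generates a complete study: a packed gene complement
(2–8 exons, random strand, minimum intergenic gap 2.5 kb), peaks placed in
promoter / exon / intron / intergenic positions, negative-binomial counts
(gamma–Poisson, dispersion 0.05, two replicates per condition), peak
sequences with planted PWM instances, binding-site sets, the two DE
tables, and per-base cut tracks.  Defaults are chosen to mirror the
qualitative structure such a study reports:

* loss effects (−2.5 to −1.2 log2) concentrate on intergenic and intronic
  peaks anchored to down-regulated genes, which start from moderate
  baselines and nearly close;
* gain effects (+0.8 to +2.0) sit on promoter peaks of up-regulated genes,
  which start from high baselines (already open, opening further);
* binding sites are placed inside the spans of bound genes, preferentially
  at their accessibility-losing peaks, with more sites on DE genes than on
  bound-but-unchanged genes; the basal ChIP set is a 40% subset of the
  agonist set, and agonist-only target genes exist;
* motif plant probability is a logistic function of the true-effect rank
  (ramp center 0.25, width 0.1 by default — a gradual landscape; tests that
  check localization of maxima use a sharper configured ramp, which is a
  property of the planted condition, not of the detector);
* planted DE calls draw adjusted p as `10^-U(2,6)` and non-calls uniform on
  `[alpha, 1]`, so the planted mode labels are exact ground truth rather
  than the outcome of a fitted test (differential-expression model fitting
  is out of scope by design);
* cut tracks are Poisson with per-base rate proportional to the peak's
  per-condition mean, accumulated over overlapping peak windows, then
  multiplied by `1 - depth` across occupied motif spans (default depths:
  WT 0.5, knockout 0.1).

Mode labels are drawn per gene i.i.d. from configured proportions
(activated 6%, repressed 3%, basal-required 8%, basal-repressed 4%,
agonist-only 2%, indirect 5%) *before* peaks are simulated and are carried
through the truth object, so planted peak effects, binding placement and DE
tables all agree with the same labels; the binding/expression stage reuses
labels already present in the truth rather than redrawing them.  Every
stage reseeds from `rng_seed` plus a fixed offset, so each stage is
deterministic on its own and the full study is reproducible bit-for-bit.

What the simulator does not emulate: read-level artifacts (duplicates,
mitochondrial reads, fragment-length structure), GC-dependent background
sequence unless configured, correlated replicate noise beyond the
negative-binomial, overlapping genes, and the enzyme's sequence bias on cut
sites.  Tests passing on this generator therefore demonstrate correctness
of the algorithms under the stated statistical structure, not performance
on real libraries — in particular, the hypergeometric landscape's null
calibration holds for rank-independent motif placement, which real
GC-driven confounding can violate.

## Numerical choices and degenerate inputs

Effect-size distributions and proportions are free parameters of the
generator, documented above, not claims about biology.  Problem sizes in
the test suite (hundreds of genes, a few thousand peaks, windows of a few
hundred kilobases) were chosen so the whole suite exercises every stage at
desk scale.  Other choices worth recording:

* count PWM input gets a pseudocount of 0.5 per cell; probability input is
  smoothed only if it contains zeros, so probability matrices round-trip
  through the JASPAR writer unchanged at the written precision;
* the demo PWM set (`defaultPWMs()`) is built in code from canonical
  consensus strings (DR4/DR1 repeats, NF-Y CCAAT, CTCF, FOXA, C/EBP, ETS,
  HNF1, HNF6) at dominance 0.95 — synthetic matrices for simulation and
  demonstration, not a curated database;
* empty gene lists annotate everything as intergenic with `NA` distances;
  genes without overlapping peaks are excluded from gene-body summaries
  and counted in the log; empty mode segments produce reports with tests
  suppressed rather than errors;
* zero-width peaks, negative counts, malformed intervals, conflicting DE
  duplicates and out-of-range p-values are rejected at the I/O boundary
  with errors naming the file and row;
* all interval arithmetic lives on `GRanges` (1-based, closed); BED and
  other 0-based dialects are converted exactly once, on read and write.

## Limitations

The enrichment statistic ignores sequence composition; the similarity
metric is permissive for short motifs; the footprint module does not model
enzyme bias; and the classifier's `other_direct` cell deliberately absorbs
same-direction responses that a four-segment display would hide.  All
quantitative statements in this vignette are computed by the package's test
suite or by `scripts/acceptance.R`; neither this document nor the README
reports numbers the code does not produce.
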