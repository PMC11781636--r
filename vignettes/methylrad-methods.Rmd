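---
title: "Models and methods behind methylrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylrad)
```

# The assay and its quantitative model

MethylRAD-style profiling relies on FspEI, a methylation-dependent
restriction enzyme: it cuts only where its recognition site carries a
methylated cytosine, releasing a short DNA tag per cut. Sequencing the
pool of released tags therefore samples sites in proportion to their
methylation level. Two site classes are distinguished by sequence
context: CCGG (the mCG context) and CCWGG with W ∈ {A, T} (the mCHG
context; a CCCGG occurrence is recognized through its embedded CCGG, so
only CCAGG and CCTGG are CCWGG sites). The modified cytosine is the
second C of the motif, and the package anchors every site at that base.

The package treats tag depth as a relative — not absolute — methylation
measure. Depth must be normalized within each library, which is done as
reads per million: `RPM = depth / library size × 1e6`, where the
library size is the number of clean reads entering quantification. No
pseudocount enters the RPM itself; a pseudocount of 1 is applied only
when fold changes are computed, so fold changes stay finite without
distorting the test statistic.

## Electronic digestion

`enumerate_sites()` scans both strands of the reference for all
expanded motifs. The motif set {CCGG, CCAGG, CCTGG} is closed under
reverse complement, which has two structural consequences the test
suite asserts: every CCGG locus is a +/− site pair, and a CCAGG site on
one strand implies a CCTGG site on the other at the same locus. `N`
bases never match (conservative site calling). Coordinates are 0-based
and half-open everywhere in the package; BED output is native, and GFF3
input is converted on read. This removes the off-by-one ambiguity that
otherwise creeps into promoter and feature arithmetic.

The sequenced fragment of a site is modeled as a fixed-length window
(default 15 nt, configurable within the assay's 13–17 bp
size-selection range) starting at the motif start on the site's strand.
The enzyme's true two-sided cut offsets are not publicly specified at
base precision; at the scale this package works, any fixed window that
identifies the site uniquely is equivalent, and the window length is a
parameter rather than a claim about enzyme chemistry. Tags shared by
identical sequence contexts are kept but flagged ambiguous, and reads
matching them are discarded as multi-mapping during quantification —
the same contract a unique-alignment filter enforces.

## Read QC ladder

Libraries are summarized by a six-stage accounting ladder: raw reads;
norm (after depth-equalizing subsampling, interpreting the
normalization column of the published per-library summary — uniform
sampling without replacement under a fixed seed); adapter (after 3'
adapter trimming, with reads trimmed to nothing dropped); enzyme (reads
containing an expanded motif in either orientation); range (length
within 13–17); and clean. The clean filters follow the published
wording as literally as possible: a read is discarded if more than 8%
of its bases are N (strict >), or if the fraction of bases below Phred
30 reaches 15% (inclusive ≥ — the quoted parenthetical is ambiguous
about strictness, and the inclusive reading is the more conservative
filter), or if it lacks a recognition motif. The three per-read
predicates are independent, so the final clean set does not depend on
filter order. The percent column is `clean / norm × 100` rounded
half-up to two decimals; both the ratio and the rounding rule were
chosen because they exactly reproduce every percent value in the
shipped per-library summary table.

## Differential testing

Counts (site tag depths or gene read counts) are compared between two
groups with a self-contained negative-binomial test in the classic
count-model style:

* **Size factors** are median-of-ratios: sample j's factor is the
  median over features of `count / geometric mean across samples`,
  over features positive in every sample. The test suite cross-checks
  this against an independent reference implementation.
* **Dispersion** is per-feature method-of-moments on normalized
  counts, `α = max(0, (v − m) / m²)` with v the within-group pooled
  variance, floored at zero (Poisson). No trend fitting or shrinkage is
  applied: the paper-scale contract is the NB test itself, and the
  bare estimator keeps the test checkable against a permutation
  oracle.
* **The test** conditions on each feature's total count T and asks
  whether the observed split between the groups is compatible with
  equal normalized means: group sums are modeled as NB with moments
  matched to the summed per-sample means/variances, and the two-sided
  p-value sums the probabilities of all splits at most as likely as
  the observed one. With α = 0 this reduces to an exact conditional
  binomial test.

Calling applies `|log2FC| > 1` (strict) and `p < 0.05` (strict). The
methylation arm gates on raw p-values and the expression arm on
BH-adjusted ones; both are switchable, because the source methodology
states both conventions in different places and the package exposes the
choice instead of hiding it. Hyper plus hypo always equals the number
called — an identity the suite asserts on every run.

**Calibration design.** The null calibration check draws 2,000
independent Poisson(50) features over 5 + 5 samples and measures the
fraction rejected at α = 0.05, expecting it inside [0.03, 0.07]. Five
replicates and mean 50 put the check in the regime the test actually
operates in (the recovery analyses also use 5 replicates; 50 is a
well-covered site depth); with 3 replicates and low means the exact
test's discreteness plus dispersion-estimation noise push rejection
rates toward the bottom of that window, which is a property of the
classic estimator, not a bug. The permutation oracle compares the NB
p-value with an exhaustive label-permutation p (252 relabelings at
n = 5 + 5) on clearly separated fixtures, where both distributions are
smooth; for central splits the permutation distribution is too coarse
for a meaningful pointwise comparison.

## Annotation

Each site (anchored at its modified cytosine) receives exactly one
feature with precedence 5'UTR > 3'UTR > exon > intron > upstream >
intergenic: UTRs outrank exon because they are sub-exonic annotations,
and genic context outranks the 2-kb upstream flank. The gene's strand
governs the upstream direction. The promoter is defined as the 2 kb
immediately upstream of the TSS, half-open at the TSS (a site exactly
at the TSS is excluded); a site may serve several genes' promoters and
is counted for each, avoiding silent data loss at the cost of
non-disjoint promoter sets. Metagene profiles map the 2-kb upstream
flank and the 2-kb downstream flank onto fixed-width bins (20 each) and
the gene body onto 40 length-normalized bins, reflecting minus-strand
genes so bins always run 5'→3'; the per-bin value is the mean site
signal within a gene, averaged over genes contributing to the bin.
Genes with fewer body bases than body bins are dropped with a warning.

## Methylation–expression integration

A gene's promoter methylation is the per-sample mean RPM over its
promoter sites (max and per-site modes are available; the aggregation
rule is a package choice, as source methodologies rarely state one).
Pearson correlation with expression is computed across all samples of
both groups pooled — with three replicates per group, pooled
correlation is the only workable design — on `log2(x + 1)`-transformed
normalized abundances, the standard scale for right-skewed RPM/CPM
values (the raw-scale correlation of exponentially linked variables is
attenuated by curvature, not by noise). Selection requires, all strict:
`r < −0.8`, `p < 0.05`, a DEG call, and at least one promoter DMS.
Quadrants classify the joint direction of change: (expression up,
methylation up) → 1, (down, up) → 2, (down, down) → 3, (up, down) → 4;
negatively coupled genes land in quadrants 2 and 4.

## Enrichment

Over-representation uses the upper-tail-inclusive hypergeometric
probability `P[X ≥ k]` of k study hits in a term of size K against a
background of size N with a study set of size n; `k = 0` gives p = 1.
Annotations come from GMT files; nothing is downloaded, because
term-to-gene maps are database-version dependent and enrichment output
is only comparable within one annotation release. Display rules mirror
the assay's reporting conventions: GO terms with more than 2 study hits
are sorted by −log10 p within each of BP/CC/MF and the top 10 per
namespace are shown; pathways use the same filter and sort with a
single top-20 cap. BH-FDR is reported alongside raw p; the display
rules use raw p as stated.

# The synthetic-data generator

The generator exists so every stage can be exercised end to end with
known ground truth. Its defaults emulate the profiled study design and
scale:

* two groups of three replicates (`SQ_1..3` young reference,
  `SL_1..3` aged comparison), configurable upward for power analyses;
* baseline site methylation ~ Beta(2, 5) (mean ≈ 0.29, right-skewed,
  as expected for sparse methylation), clipped away from 0 and 1;
* `mean_depth = 75` expected tags at level 1, so the realized mean
  site depth is ≈ 21 — the published mean CCGG site coverage;
* 10% of sites carry a 4-fold shift in the aged group (the >2-fold
  calling rule with headroom), split evenly hyper/hypo and clipped to
  (0, 1]; clipping means a high-baseline hypermethylated site cannot
  realize the full fold, so the recorded ground truth stores each
  planted site's realized log2 shift and recovery is evaluated on
  sites whose shift is actually ≥ 2 log2 units;
* tag counts are negative binomial (dispersion 0.2), not Poisson, so
  the dispersion path of the test is exercised;
* a subset of promoter-bearing genes (15%) is negatively coupled:
  their promoter sites are shifted as a block (hyper-coupled baselines
  are capped at 0.8/fold so the planted fold is realizable on the
  level scale) and receive shared per-sample lognormal variation
  (sd 0.3); expression log2 means then follow the gene's per-sample
  promoter methylation with slope −1 plus Gaussian noise (sd 0.15) on
  top of NB counting noise. The realized methylation–expression
  correlation is measured, never assumed; the generator's contract is
  that ≥ 80% of coupled genes realize r < −0.8 at 20 samples, and the
  suite asserts it;
* planted QC failures at 4% each: N-rich reads (2 of 15 bases set to
  N, > 8%), low-quality reads (3 bases at Phred 20, ≥ 15% under Q30)
  and motif-less random reads — each failing exactly one ladder stage
  — plus a 20% adapter-carrying fraction exercising trimming;
* everything is deterministic under one master seed, byte-identically
  so for the written FASTA/GFF3/FASTQ outputs.

What the generator does **not** emulate: real genome composition (CpG
islands, repeats — tags are unique by construction far more often than
in a mammalian genome), sequencing substitution errors (QC failures are
planted, not emergent), batch effects, biological covariance between
neighboring sites, and isoform structure. Passing recovery tests on
synthetic data therefore demonstrates the correctness and calibration
of the statistical machinery under the stated model, not performance on
real mouse lens libraries.

# Problem sizes and runtime

Default simulations use 2 × 50 kb chromosomes with 60 genes (~1,000
stranded sites, ~25k reads per sample), which keeps a full pipeline run
under two minutes on one CPU. The recovery analyses use 5 replicates
per group for differential sites (three per group, the study design, is
honestly reported as underpowered for site-level 4-fold shifts at
moderate depth) and 10 per group for the coupling analysis, where a
meaningful Pearson threshold of −0.8 needs ~20 observations. The null
calibration uses 2,000 features.

# Known limitations

* Exact unique-tag matching replaces read alignment; it preserves the
  unique-mapping contract but does not model mismatches or indels.
* The dispersion estimator is deliberately simple; with two or three
  replicates it is noisy, making the test conservative near the null.
* Promoter aggregation ignores within-promoter heterogeneity unless
  the per-site mode is used.
* Whether the original analyses gated differential sites on raw or
  FDR-adjusted p-values is not determinable from the source; both
  options are exposed, with raw p as the methylation default.
* The published normalization ("norm reads") is undefined in the
  source; depth-equalizing subsampling is an interpretation and is
  labeled as such.
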