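---
title: "Methods: chromatin-state transitions from promoter tiling ChIP-chip"
author: "chromtrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state transitions from promoter tiling ChIP-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtrans)
```

# Overview

`chromtrans` analyses promoter tiling-array ChIP-chip profiles of two
histone marks — H3K4me3 (active promoters) and H3K27me3 (polycomb
repression) — in paired normal/tumor samples. The pipeline has five stages:
signal processing, enriched-region calling, chromatin-state and transition
classification, promoter annotation, and enrichment/expression statistics.
A synthetic-data generator with planted ground truth makes every stage
testable offline; this vignette documents the model, the parameters, and
the design choices made where the method description left room.

# Signal model

Each (mark, sample) experiment consists of two ChIP and two input replicate
arrays over the same probes. The four arrays are quantile normalized
*together* and each rescaled to a median intensity of 200 — quantile
normalization assumes the four arrays interrogate the same underlying
intensity distribution, which holds within a replicate/input quadruple.
Ties in quantile normalization receive the mean of the tied sorted-column
means (average-rank interpolation, the standard convention).

Replicates are merged with a sliding window of 301 bp (bandwidth 150 bp):
the value at a probe is the median over all replicate values at probes
whose *center* lies within 150 bp of that probe's center, boundary
inclusive. Merge happens before the ratio: the per-probe signal is
log2(merged ChIP / merged input). Because chip and input medians are taken
over the same window of the same probes, probe-affinity effects largely
cancel in the ratio.

The enrichment statistic is a windowed Z-score

$$Z(p) = \frac{w(p) - \mu}{\sigma},$$

with $w(p)$ the mean log2 ratio of probes within 75 bp of $p$'s center
(a 150 bp window) and $\mu$, $\sigma$ the mean and standard deviation of
the *single-probe* log2 ratios of the whole array. Two conventions are
fixed here and exposed as flags:

* $\sigma$ is the **population** standard deviation by default
  (`signal_params(sd_type = )`);
* the reference distribution is the merged track of the same array — not
  pooled across arrays. Each (mark, sample) array stands on its own, which
  keeps Z-scores comparable within an array but means a mark that covers a
  large fraction of the array deflates its own Z-scores (see *Synthetic
  data*, below).

Degenerate inputs fail loudly: non-positive merged values (impossible after
normalization of positive intensities), zero-variance arrays, and
mismatched probe sets are errors, not silent NA.

# Region calling

Probes with $Z \ge 6$ (boundary inclusive) are *enriched*. Regions are
formed in four ordered steps:

1. an enriched probe is disqualified unless a measured probe lies within
   110 bp on *both* sides (evaluated before region formation);
2. surviving enriched probes with consecutive center-to-center gaps of at
   most 110 bp form runs; runs with at least 2 enriched probes become
   regions, whose members are all measured probes between the outermost
   enriched probes;
3. regions are prolonged with measured probes within 75 bp of their tails;
4. regions closer than 1000 bp (strictly) are merged, transitively.

All probe-to-probe distances are center-to-center and boundary inclusive —
the method statement does not fix either convention, so one is used
consistently for the gap, flank, and prolongation rules. Merging is a
transitive closure (chains of regions each within 1000 bp collapse); it is
idempotent and order-independent.

Prolongation runs to a **fixpoint** by default: a probe absorbed on one
pass can pull in the next. On a contiguously tiled span (35 bp spacing)
this absorbs every probe until the first inter-probe gap above 75 bp, so
called regions extend to the boundaries of the tiled promoter interval.
This widening does not affect state calls (they depend on shared probes
and Z-scores, and promoters are isolated by design), but users who want
tight boundaries on dense designs can set
`region_params(prolong_single_pass = TRUE)`, which only absorbs probes
within 75 bp of the original tails.

# States, bivalency, transitions

A **bivalent region** is a K4/K27 region pair of one sample sharing at
least 3 probes of which at least 2 are enriched. The method statement does
not say whether the enriched shared probes must be enriched in both marks;
the default is the stricter reading (2 enriched shared probes in *each*
mark), with `state_params(biv_enriched_in = "either")` for the laxer one.

A **locus** is a maximal connected component of probe-sharing regions
pooled across both marks and both conditions. This joint object makes the
normal-vs-tumor comparison well-defined when region boundaries shift
between conditions. Per condition a locus is BIV if it contains a bivalent
region, else K4 or K27 if only that mark is present, else NONE. A locus
carrying both marks without a bivalent pair is recorded as `"K4+K27"` and
flagged; it is excluded from transition classification (status `"semi"`)
rather than forced into the four-state alphabet — semi-bivalency proper is
a gene-level call.

Over the alphabet {NONE, K4, K27, BIV} there are 15 valid ordered state
pairs (16 minus NONE→NONE). The three categories are determined by how
many marks' presence changes: none (3 "kept" pairs), exactly one (8
single-mark gains/losses), both (4: K4↔K27 and BIV↔NONE).

Two guards keep transitions honest:

* a **kept** mark needs a normal/tumor region pair sharing ≥ 3 probes with
  ≥ 2 enriched in *both* conditions;
* a **changed** mark needs $|\max Z_\text{normal} - \max Z_\text{tumor}|
  \ge 3$ over the locus.

The ΔZ rule is deliberately applied to each mark whose called presence
changes — this is the reading under which it prevents calling a transition
when the two conditions sit just on opposite sides of the $Z \ge 6$
cut-off (e.g. 6.2 vs 5.8). The alternative reading (requiring $Z < 3$ in
the absent condition) is *not* the default; loci failing the guards are
emitted with status `"unresolved"`, never silently dropped.

# Annotation

Regions associate to transcripts within ±2.5 kb of the TSS, strand-aware:

* rule (i), *intragenic*: the region overlaps the transcript body by
  ≥ 1 bp and its nearest edge starts at most 2.5 kb downstream of the TSS
  (a region spanning the TSS qualifies);
* rule (ii), *upstream*: the region overlaps **no** transcript body and
  ends within 2.5 kb upstream of a TSS. Intragenic positioning anywhere
  blocks rule (ii).

"Nearest edge" (rather than midpoint) defines the distance; the rules are
applied per transcript independently, and gene-level results aggregate by
gene symbol. Gene classes follow the associated marks: BIVALENT if any
associated region is bivalent, SEMI_BIVALENT if both marks are present
without a bivalent region, otherwise K4, K27 or NONE.

# Statistics

* **Term enrichment**: one-sided hypergeometric tails
  ($P[X \ge k]$ / $P[X \le k]$) against the whole term-map universe,
  Bonferroni-corrected over tested terms. The tail identity
  $p_\text{over} + p_\text{under} = 1 + P[X = k]$ holds exactly and is
  tested against brute-force enumeration.
* **Clustering of significance profiles**: signed scores
  ($+(-\log_{10} p_\text{over})$ for over-representation,
  $-(-\log_{10} p_\text{under})$ for under-representation, clipped at 300
  to keep distances finite), Euclidean distances, Ward agglomeration
  (Ward.D2, i.e. squared-distance updates).
* **Group expression shifts**: per *patient*, the mean expression of the
  group's genes in tumor minus normal; one-sided paired t-test over
  patients (n = number of patients). Pooling per-gene differences instead
  would overstate independence; the per-patient unit is the default.
  Zero-variance differences return p = 0.5 (all-zero) or 0/1 by sign.
* **Differential expression**: per-gene paired t-tests with
  Benjamini–Hochberg correction at adjusted p < 0.001. Moderated
  statistics are deliberately not reimplemented; an optional lightweight
  empirical-Bayes variance squeeze (`moderate = TRUE`, pooled prior
  variance, fixed prior df) is available, and the unmoderated t is
  cross-checked against a paired `limma::lmFit` in the test suite.
* **Overlap tests**: hypergeometric overlap of transition groups with
  up/down-regulated genes (p < 0.05) and of gene groups with
  hypermethylated gene lists (p < 0.01), restricted to the universe of
  genes present on both platforms.

# Synthetic data: the stated world

The generator emulates an Affymetrix-style promoter design: 25 bp probes
every 35 bp, tiled from 7.5 kb upstream to 2.45 kb downstream of each TSS
(284 probes per promoter), promoters non-overlapping with ≥ 20 kb between
tiled spans so annotation is unambiguous by default.

Background probe affinities are log-normal (meanlog = log 200,
sdlog = 0.5), shared across arrays; replicate noise is multiplicative
log-normal with sd 0.25 on the natural-log scale (a ~25% replicate CV,
typical for array intensities). Enrichment is multiplicative on the linear
scale — fold-change 8 by default — so the expected log2 ratio over a
planted interval is exactly 3. Planted mark intervals span ±300 bp around
the TSS (17 probes); a bivalent promoter gets identical K4 and K27
intervals, guaranteeing the shared-probe requirement.

One structural property matters: because Z-scores are standardized against
the whole array, the attainable Z at planted probes is capped near
$\sqrt{(1-f)/f}$ where $f$ is the planted fraction of probes. Marks must
therefore stay sparse (a few percent of the array), which the default
world respects: in the 200-promoter acceptance scenario each of the 15
transition types is planted on 4 promoters (60 marked, 140 unmarked), so
$f \approx 1\%$ per mark and condition and planted windows reach
$Z \approx 8$–10. The original arrays, with 25,500 promoters and regions
covering a small fraction of probes, sit in the same regime.

The expression simulator plants baselines by normal state (K4 genes log2
≈ 8, unmarked ≈ 6, K27/bivalent ≈ 4 — active marks expressed, repressive
marks silent), patient effects (sd 0.3), residual noise (sd 0.5, 24
patient pairs), and a configurable per-gene tumor shift (defaults: +1 for
K4-in-tumor genes, −1 for K27/BIV-in-tumor — hyperactivation and
hypersilencing). The methylation simulator samples genes into a
hypermethylated list at 5× the 5% background rate when they carry K27 (or
bivalency) in the normal condition.

What the generator does **not** emulate: sequence effects and probe GC
bias, copy-number aberrations, batch effects between conditions,
overlapping transcripts (available only by constructing custom transcript
tables), and broad multi-promoter K27 domains. A green end-to-end test
therefore establishes the correctness of the pipeline's logic under
idealized array noise — not its robustness to every artefact of real
tiling arrays.

# Numerical choices and degenerate cases

* Coordinates are 0-based half-open everywhere (BED/bedGraph on disk,
  knownGene-style `txStart` in transcript tables).
* All thresholds are boundary-inclusive where the method says "within" or
  "at least" (Z = 6.0 is enriched; 110 bp gaps and 75 bp prolongation
  distances are allowed; regions exactly 1000 bp apart do *not* merge —
  "less than" is strict).
* `sd_type`, `biv_enriched_in`, `prolong_single_pass`, `moderate` expose
  the documented interpretation flags; defaults are stated above.
* Empty inputs return empty, typed tables; invalid inputs (non-positive
  intensities, truth intervals outside the tiled span, foreground genes
  outside the universe, unknown gene symbols in effect vectors) raise
  errors naming the offender.

# Limitations

* Region boundaries on contiguously tiled designs are dominated by the
  prolongation fixpoint (see above); counts and states are unaffected.
* The Z-score reference is per-array; comparing absolute Z values across
  arrays with very different enrichment fractions is not meaningful —
  transitions rely on ΔZ within a locus, which is robust to this.
* The statistics module takes the term map as given (no GO DAG
  propagation) and implements ordinary paired t-tests, not moderated ones.
* Acceptance-style recovery rates are properties of the synthetic world;
  they are not claims about sensitivity on real arrays, whose noise
  magnitudes the method description does not state.
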