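---
title: "Models and methods behind NotIPanel"
author: "NotIPanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind NotIPanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NotIPanel)
```

## The assay and its data model

A NotI-microarray interrogates clones carrying a NotI restriction site
(GCGGCCGC) in CpG-rich regions. Loss of NotI digestibility at a clone
signals methylation and/or deletion of the surrounding locus; the assay
cannot separate the two mechanisms, and neither does this package. Each
(sample, locus) cell therefore carries one of five states:
heterozygous loss (`HET_LOSS`), homozygous loss (`HOM_LOSS`),
amplification/demethylation (`GAIN`), `UNCHANGED`, or `MISSING`. The two
loss states jointly count as "aberrant" in every downstream statistic.

`AberrationExperiment` holds these calls as the single assay of a
`SummarizedExperiment`: loci (NotI clones) in rows with clone id, gene
symbol and cytoband annotation; samples in columns with a `group` label
— `adenoma`, `cancer_le7` (carcinoma, Gleason score at most 7),
`cancer_gt7` (aggressive carcinoma, Gleason above 7), or `normal` — and
an optional Gleason score that the validity method checks against the
group.

The reference design emulated throughout is a prostate-tumor cohort of
15 adenomas, 14 nonaggressive carcinomas and 4 aggressive carcinomas
assayed over 180 chromosome-3 clones. Its published per-group
frequencies (`referenceFrequencyTable()`, `referenceContrastCounts()`)
are built into the package as both simulation defaults and exact test
fixtures. One published cell ("80% (14/15)") is internally inconsistent;
the tables therefore keep percent and raw counts side by side, percent
driving simulation and raw counts driving the contingency
reconstructions.

## Frequency tables and filters

`groupFrequencies()` counts losses per (locus, group) against the *full*
group size: missing calls stay in the denominator as non-aberrant. This
follows the reference tables, whose denominators always equal the group
sizes (15, 14, 4, 29), so missing cells were evidently not dropped
per locus. `filterAlteredLoci()` keeps loci whose pooled frequency of
*any* change — gains included, as the assay's change census counts them —
strictly exceeds the cutoff (default 10%). `rankLociTable()` orders loci
by pooled loss frequency with a lexicographic clone-id tie-break, so the
ranking is a deterministic permutation of the loci.

## Exact contingency testing

For each locus, `compareGroups()` forms the 2x2 table of aberrant
versus non-aberrant samples across two pooled, disjoint group specs and
computes the two-sided Fisher exact P value under the point-probability
rule: the sum over all tables with the observed margins whose point
hypergeometric probability does not exceed the observed one (relative
tie tolerance 1e-7). This convention — the one implemented by
`stats::fisher.test` — reproduces every reported contrast P value of the
reference cohort to the printed three decimals, which is why it was
chosen over the conditional-minimum-likelihood or tail-doubling
variants. The chi-square statistic is reported alongside but never
drives the significance flag, and tables with a zero margin report a
flagged `p = 1` rather than an undefined statistic. Raw P values are
compared against `alpha` (default 0.05) with no multiplicity
correction, matching the source analysis; Benjamini-Hochberg FDR is
available as an optional column. Report rendering prints three decimals
and collapses anything below 0.001 to "<0.001", the convention of the
reference tables (which print "<0.001" for P = 0.0007).

## Count-threshold marker panels

A `MarkerPanel` is a gene set plus a cutoff `t` on the number of
aberrant panel loci, applied in one of two directions: positive when
the count is at least `t`, or — for panels whose markers are enriched in
the *negative* class — positive when the count falls below `t`. The three
shipped panels (`defaultPanels()`) are the published rules: tumor
detection (6 markers, two or more), aggressiveness (5 markers, three or
more), and adenoma-versus-carcinoma (5 markers, fewer than two calls a
sample cancerous). Missing calls never count as aberrant, consistent
with the frequency tables.

The detection panel's negative class is a tumor-free `normal` group.
The reference matrix contains no normal columns (its normals were a
pooled hybridization reference), so `defaultDesign(normalSamples =)`
can append a normal group simulated at the background aberration rate;
without it the detection panel is not evaluable on a synthetic cohort.

### Gini interval and lift curves

The ranking score behind each panel is the integer marker count, which
over five or six markers ties heavily. Every tie ordering induces a
different cumulative-positives lift curve, so the Gini coefficient
(`2 * AUC - 1` of the induced ROC) is an *interval*, not a point: the
most favorable ordering places positives first within each tied block,
the least favorable places them last, and `giniInterval()` returns both
extremes. Untied scores collapse the interval; a single shared score
spans the full `[-1, 1]`. This tie-ambiguity reading is the only one
under which a count score can have a Gini "range" at all.

### Exhaustive search instead of SVM retraining

The original marker sets were reportedly seeded by a support vector
machine whose kernel, features and training protocol are unspecified —
and whose published deliverables are, in the end, plain count-threshold
rules. Rather than guess at an unreproducible trainer,
`searchPanels()` exhaustively enumerates the same rule family: all
size-`k` subsets of a candidate list (capped at 30 loci; pre-filter
with `compareGroups()`), all thresholds, both directions. Rules are
ranked by accuracy, ties broken by worst-case Gini and then by the
lexicographic marker list, which makes the output deterministic and
invariant to candidate order. The worst-case Gini is evaluated lazily,
only for rules competing at the accuracy boundary of the requested
top-N, which keeps the C(20,5)-scale searches used in validation fast.

## Network enrichment analysis

`FunctionalNetwork` wraps an undirected simple igraph over gene
symbols, assembled by `loadNetwork()` from FunCoup-style scored edge
lists (kept when the confidence score strictly exceeds 0.5 by default)
unioned with curated edge lists (kept unconditionally). Enrichment
between a marker set and a pathway is measured by counting links:
either direct edges between the sets (each edge once, including the
within-set case A = B) or, in indirect mode, shared network neighbors
summed over unordered cross-set gene pairs.

Two null models are provided because the underlying statistic is not
uniquely pinned down by its description:

* **Permutation** (default): the network is regenerated by
  degree-preserving double-edge swaps (at least 10 attempted swaps per
  edge), the count recomputed each time, and the one-sided P value
  taken as the add-one-smoothed empirical upper tail. This matches the
  "random network with the same topological properties" reading. When
  every permuted count equals the observed one — e.g. an isolated
  clique, which double-edge swaps map to itself — the z score is
  undefined and the result is flagged degenerate rather than inflated.
* **Analytic** (direct mode only): the configuration-model expectation
  `D_A * D_B / (2m)` for disjoint sets, with the overlap-aware
  correction (edges inside the shared genes are counted once, so the
  shared-degree term enters as `D_I^2 / (4m)`), and a Poisson upper
  tail. It is orders of magnitude faster and is the null used in the
  screening validations, where the permutation floor
  `1/(nPerm + 1)` cannot reach small FDR thresholds at practical
  permutation counts.

`neaScreen()` tests every marker-set/pathway pair plus each set against
itself, applies Benjamini-Hochberg FDR across the whole family, and
reports relations with at least `minLinks` observed links (default 10)
below the FDR threshold (default 0.01).

## The synthetic cohort generator

No per-sample call matrix is published for the reference cohort, so
every stage is validated against simulation. The generator draws each
cell independently: missing with `missingProb`; otherwise a gain with
the cell's gain probability; otherwise a loss with the (locus, group)
aberration probability, homozygous with probability `homFraction`;
otherwise unchanged. Independent Bernoulli cells match the marginal
frequencies — the only distributional facts published — and make the
operating characteristics of count rules analytically predictable as
binomial tails, which the tests exploit. What the generator does *not*
emulate: inter-locus correlation (co-methylation of neighboring clones
is real but unquantified in the source), probe effects, and any
intensity-level noise; passing tests therefore validate the pipeline's
statistics, not the biology of any particular cohort.

Defaults, and where they come from:

* Per-(locus, group) aberration probabilities: the published percent
  frequencies of the 50 top-ranked loci plus the 11 additional contrast
  loci (pooled rates applied to both pooled groups where the split is
  unreported); remaining loci at a background rate of 0.05. Without
  the contrast loci, the shipped aggressiveness and grade panels would
  reference loci absent from the default cohort.
* `homFraction = 461/(461+1163) = 0.284`: the cohort's homozygous share
  of its 1624 loss calls — the only published evidence on the split.
* `gainProb = 0.001`: 24 gains among roughly 33 x 180 calls, capped at
  `1 - aberrationProb` per cell so probabilities stay coherent.
* `missingProb = 0.02`: the published call matrix figure shows sparse
  missingness but no rate; 2% is a typical NotI-array dropout and the
  value is freely configurable.

Because gains are drawn before losses, the loss frequency among
informative calls is `(1 - gainProb) * p`; recovery checks therefore
measure frequencies over informative (non-missing) calls, where the
0.1% gain attenuation is far inside sampling noise.

## Problem sizes used in validation

Validation problem sizes were chosen for statistical resolution, once:

* Frequency recovery: 10,000 samples per group; each of the 540
  (locus, group) cells should sit within 3 SE, and since roughly 0.27%
  of cells exceed 3 SE by chance (about 1.5 of 540), the check bounds
  the exceedance count by its binomial tail rather than asserting
  every cell.
* Binomial operating points: 10,000 samples per class against the
  closed-form binomial tails, within 3 SE.
* Planted-panel recovery: 5 informative loci (0.9 versus 0.05) among
  15 nulls, 500 samples per class, 100 replicates. The size follows
  from power: the accuracy gap between a 3-true and a 5-true panel is
  about 2.7 percentage points, which only dominates sampling noise —
  across the roughly 1,000 competing contaminated subsets — from a few
  hundred samples per class.
* NEA: planted 25-gene module (within-module edge probability 0.5) in
  a 300-gene background at 0.01, screened over 20 seeds; null
  calibration of z over 200 Erdős–Rényi trials at 100 permutations
  each.

## Known limitations

* The package starts from called states; raw two-channel intensities,
  array segmentation and normalization are out of scope.
* Methylation and deletion are conflated by design of the assay.
* The published per-sample matrix exists only as a figure, so the
  published panel percentages (94/94, 100/97, 93/73) cannot be
  recomputed from real data; the package instead shows that the same
  rules, applied to cohorts simulated at the published frequencies,
  land near those figures, and that all metric identities hold exactly.
* How the aggressiveness panel's five markers were chosen from the
  nine significant loci — and why LRRC58 enters the grade panel despite
  not reaching significance — is not algorithmically specified anywhere;
  `searchPanels()` provides a transparent, reproducible alternative
  rather than a reconstruction.
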