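---
title: "Clinical analysis of pan-cancer chromatin accessibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical analysis of pan-cancer chromatin accessibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaccess)
```

## Overview

`chromaccess` implements a pipeline for asking what chromatin accessibility,
measured by ATAC-seq across a multi-cancer patient cohort, says about
clinical variables. It has five analysis stages plus a synthetic-cohort
generator:

1. **Curation** — build one fixed-width, non-overlapping "pan-cancer" peak
   set from per-sample peak summits.
2. **Normalization** — turn a raw peak-by-replicate fragment-count matrix
   into a peak-by-sample log2 intensity matrix.
3. **Landscape** — score every chromosome segment for unusually dense
   accessibility against a permutation null.
4. **Association** — test promoter peaks for differential accessibility
   between two patient groups (sex, age, stage, lung histology, breast
   cancer molecular subtype).
5. **Survival** — associate each promoter peak's intensity with overall
   survival by Cox regression and median-split Kaplan–Meier analysis.

Everything operates in 1-based inclusive genomic coordinates in memory;
BED files are converted from/to 0-based half-open form only at I/O
boundaries.

## Peak curation

ATAC-seq peak callers report a summit (the base of maximal signal) and a
significance score per peak. Comparing intensities across loci and samples
requires peaks of one width, so each summit is extended by 250 bp on both
sides to a fixed 501 bp window. Windows that would cross a chromosome edge
are dropped, not clipped — a clipped peak would break the fixed-width
invariant that every downstream intensity comparison relies on.

Overlapping peaks are resolved by **iterative overlap removal**: keep the
highest-scoring remaining peak, discard everything overlapping it by at
least one base, repeat. Overlap means ≥ 1 shared base between 1-based
inclusive intervals. Score ties are broken by smaller start, then smaller
end, then chromosome name, which makes the procedure deterministic and
independent of input order; the implementation is a single score-ordered
sweep, which is provably equivalent to the literal remove-as-you-go loop
and is cross-checked in the tests against a naive reference on a thousand
random instances.

The full pan-cancer assembly is three-staged:

* per sample: scores are rescaled to sum to 10^6 (correcting for sequencing
  depth and sample quality), then overlap removal;
* per cancer type: the sample sets are pooled, rescaled to sum to 10^6
  within the cancer type, and overlap removal is applied again. The
  renormalization constant is not dictated by the procedure itself; we
  mirror the per-sample per-million rule so scores remain comparable across
  stages;
* pan-cancer: the per-cancer sets are pooled and filtered — peaks
  supported by fewer than two samples (support = number of samples whose
  peak set overlaps the candidate by ≥ 1 bp), peaks on chrY, and peaks
  overlapping any N-masked (assembly-gap) interval are removed — followed
  by a final overlap removal.

The output is pairwise non-overlapping, all 501 bp, and reproducible.

## Count normalization

Raw fragment counts are transformed in four steps: add a prior count of 5
to every cell; scale each column to counts per million of its prior-added
total (so each column sums to 10^6); log2; quantile normalization. The
prior damps the relative variance of low-count peaks. The CPM denominator
is the prior-added column total — the natural library-size proxy when no
external library size is available. Quantile normalization forces all
columns to share one value distribution while preserving within-column
ranks; ties receive the mean of the reference values at the ranks they
span (the standard convention, delegated to `limma::normalizeQuantiles`
and pinned by exact 2×2 and 3×2 oracles in the tests). Technical
replicates are averaged into samples *after* normalization, following the
order of operations of the source protocol; the result is the "peak
intensity" matrix used everywhere downstream. Normalization is by default
across all columns jointly; per-cancer-type normalization can be performed
by subsetting columns before the call.

## Promoter definition

The promoter is the window from 1000 bp upstream to 100 bp downstream of a
gene's TSS. The source convention does not say how to treat minus-strand
genes; we orient the window by transcription (mirroring it in genomic
coordinates on the minus strand), the standard promoter convention. A peak
belongs to a gene's promoter when its *summit* lies in the window; the
reported distance to TSS is signed and transcription-oriented (negative =
upstream). When a summit falls in two genes' windows it is assigned to the
gene with the smaller |distance|, with remaining ties broken by gene ID —
deterministic and consistent with nearest-gene annotation practice.
Genomic-context labels from the count matrix collapse to four categories:
promoter; distal/enhancer; intron; other (exon and UTRs). Association and
survival stages test promoter peaks only by default (`promoter_only` flag),
since the promoter is where accessibility most directly couples to
transcription.

## Permutation landscape

Each chromosome is divided into 92 equal-length, half-open segments
(segment length therefore varies across chromosomes; a summit exactly on a
boundary belongs to the following segment). The observed statistic per
segment is the summit count divided by segment length; summit assignment
prevents a peak from being counted in two segments. Under the null, every
peak is relocated uniformly at random — chromosome drawn proportional to
length, position uniform — which operationalizes "permuting chromosome
numbers and genomic locations". A within-chromosome variant (preserving
per-chromosome counts) is available via `scheme = "within_chromosome"`.
The empirical p-value uses the add-one correction
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, so $p \in [1/(1+N), 1]$
and the score $-\log_{10} p$ is bounded by $\log_{10}(1+N)$. The default
$N = 10^6$ matches the reference procedure; the tests and desk-scale runs
use $10^3$–$10^4$, which bounds attainable scores at 3–4 but leaves the
type-I behavior unchanged (verified on a uniform synthetic peak set: the
fraction of segments with $p \le 0.05$ sits within the 3σ binomial band
around 0.05, slightly conservative because counts are discrete).

## Group association

For each promoter peak, a two-sided Mann–Whitney U test compares the two
groups of a contrast, with Benjamini–Hochberg correction across all tested
peaks. The exact null distribution is used when the smaller group has at
most 8 samples and there are no ties; otherwise the normal approximation
with tie and continuity correction — at cohort sizes of hundreds the
approximation is indistinguishable from exact. The log2 fold change is the
difference of group means on the already-log2 intensity scale (equivalently
the log2 ratio of geometric means), oriented group A over group B; this is
the scale-consistent reading of a fold change on a log-normalized matrix.
Two threshold regimes are built in: |log2FC| > 0.3 for demographic
contrasts (sex: male/female; age: median split with values equal to the
median going to the low group; stage: III/IV vs I/II, missing stages
dropped) and fold change ≥ 2 (|log2FC| ≥ 1) for the histology (LUAD vs
LUSC) and molecular-subtype (PAM50 basal vs pooled LumA/LumB/Her2/Normal)
contrasts. Swapping the groups exactly negates fold changes and swaps the
direction partition, which the tests assert.

## Survival analysis

Samples with missing or zero survival time or missing event indicator are
removed first. Each promoter peak's intensity enters a single-covariate
Cox proportional-hazards model (continuous covariate; Breslow tie
handling by default, Efron available — at these cohort sizes the
difference is negligible). Wald p-values are BH-corrected across peaks;
"prognostic" means q < 0.05. Peaks with a constant covariate or a
monotone partial likelihood (diverging coefficient) are flagged
non-estimable and excluded from the correction rather than contaminating
it. Estimates are cross-checked in the tests against an independent
Newton–Raphson maximization of the Breslow partial likelihood, and the
direction of two-group fits is checked against the log-rank direction.
The per-chromosome summary counts prognostic peaks and splits them by
hazard-ratio direction (HR > 1: higher intensity, worse survival). For
the Kaplan–Meier view, samples are split at the peak's median intensity —
values above the median form the high group; values at the median go low,
resolving the high/low wording downward — and compared by a two-sided
log-rank test. All cancer types are pooled in survival analysis, trading
type-specific effects for power, as the small per-type counts dictate.

## The synthetic cohort generator

Real pan-cancer ATAC matrices are controlled-access; the generator
produces every input the pipeline needs, with known ground truth, so the
whole chain is testable offline. Its defaults are the study conditions the
pipeline targets:

* **Cohort**: 404 samples over 23 cancer types in the reference
  proportions (breast cancer largest at 74, cervical smallest at 2);
  `cohort_scale` shrinks all types proportionally (minimum 2) for
  desk-scale runs. Sex is forced for sex-specific cancers (PRAD/TGCT male,
  BRCA/UCEC/CESC female) and random elsewhere; ages are N(59, 12²) so a
  median split lands near 59; stage is absent for the cancer types that
  lack staging and missing at 5% elsewhere; PAM50 labels follow the
  observed basal/LumA/LumB/Her2/Normal proportions within BRCA.
* **Genome**: GRCh38 chromosome lengths scaled by 1/100 (keeping relative
  chromosome sizes, hence realistic segment-length variation) with random
  N-masked intervals and a chrY decoy whose summit calls exercise the chrY
  filter. The 92-segment statistic is unchanged by the scaling.
* **Counts**: negative binomial with log-normal per-peak means
  (`meanlog = log 50`, `sdlog = 0.7`) and dispersion φ = 0.3 — the
  standard over-dispersed model for ATAC fragment counts; log-normal
  per-replicate depth factors; ~10% of samples carry two technical
  replicates.
* **Planted effects** (all on promoter peaks, mutually disjoint, recorded
  in a truth table): female-up chrX peaks with log2FC ∈ [0.5, 2] (the
  X-inactivation signature, e.g. an XIST-like locus) plus a small
  autosomal male-up set; fold-change ≥ 2 peaks for the LUAD/LUSC and
  basal/non-basal contrasts; and survival peaks whose standardized
  intensities enter an exponential-baseline hazard
  $h_i = h_0 \exp(\sum_p \beta_p z_{ip})$. Administrative censoring is
  exponential with rate $h_0 c/(1-c)$ for a target censoring fraction $c$
  (default 0.3).

One caveat the generator makes visible: when many peaks enter the hazard
simultaneously, each peak's *marginal* Cox coefficient is attenuated
relative to its planted value (omitted covariates act as frailty in a Cox
model — 20 peaks at β ≈ 0.7 left marginal estimates near 0.14). The
default therefore plants 8 + 8 survival peaks at β ∈ [0.5, 0.8], and the
chromosome-localization test uses 5 strong peaks; single-covariate
parameter recovery (the Wald-CI coverage check) is unaffected. The
generator emulates planted group differences and proportional-hazards
survival structure; it does not emulate peak-to-peak correlation,
copy-number or GC artifacts, batch effects, or tissue-of-origin intensity
profiles — passing tests demonstrate the statistical machinery, not
robustness to those real-data features.

## Problem sizes and numerical choices

Tests and the bundled analysis scripts run the 404-sample cohort with
2 000 peak loci, 10³–10⁴ permutation replicates, 200-replicate Cox
recovery and 100-replicate Kaplan–Meier power simulations; the full
pipeline completes in about half a minute on one core. All randomness
descends from a single seed (child seeds are derived arithmetically), so
identical configurations give byte-identical outputs, which the pipeline
manifest (parameter hash + input checksums) makes auditable. Empirical
p-values are never zero by construction; percentages in printed tables use
half-up rounding to one decimal; BH q-values are computed only over
estimable tests.

## Known limitations

* Unadjusted two-group tests and single-covariate Cox models — no
  covariate adjustment, stratification by cancer type, or time-dependent
  effects.
* The landscape reports segment scores, not cytoband or gene-level
  annotation.
* Peak calling itself (and read-level processing) is upstream of this
  package: inputs begin at called summits and counts.
* The BH scope for survival q-values is genome-wide across promoter peaks;
  testing a handful of pre-selected peaks against a local BH scope is
  possible by subsetting the matrix first.
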