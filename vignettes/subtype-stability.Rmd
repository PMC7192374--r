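---
title: "Centroid-correlation subtyping and subtype stability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-correlation subtyping and subtype stability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrotype)
```

## The problem

Triple-negative breast cancer (TNBC) is transcriptionally heterogeneous.
A widely used taxonomy divides it into molecular subtypes — basal-like 1
and 2 (BL1, BL2), mesenchymal (M), mesenchymal stem-like (MSL) and
luminal androgen receptor (LAR) — with an immunomodulatory (IM) signal
treated as a modifier overlaid on a subtype rather than a subtype of its
own. Assignments are made by correlating a sample's expression profile
against one reference centroid per subtype and picking the best match.
`centrotype` implements that decision procedure in full, together with
the surrounding machinery a study of subtype *stability* needs: gene
coverage gating, transcript-to-gene aggregation, preprocessing, a
nearest-shrunken-centroids trainer for deriving reduced signatures,
concordance and stability reports across classifiers and growth
conditions, and a seeded synthetic-cohort generator so that every stage
can be exercised and tested without any external download.

## The classification procedure

Each sample is processed as follows.

1. **Coverage gate.** If the fraction of centroid (signature) genes
   absent from the matrix strictly exceeds 10% (`max_missing = 0.10`),
   classification is refused — too much of the signature is missing for
   a trustworthy score. The comparison is strict: a matrix missing
   exactly 10% of signature genes still passes. Signature genes that are
   missing but below the gate are dropped from the correlation (no
   imputation); `n_genes_used` records the reduction.
2. **Preprocessing.** Linear-scale values (FPKM/RPKM, array
   intensities) become `log2(v + pseudocount)`; each gene is then
   centered (mean by default, median by option) within its batch.
   Centering is per *batch* deliberately: an additive per-gene platform
   or condition offset is removed exactly by this step, which is what
   makes calls comparable between, say, cultured cells and xenograft
   tumors profiled on different pipelines.
3. **Correlation.** Spearman's rank correlation of the centered profile
   against each subtype centroid, over the gene intersection, with
   average ranks for ties. Rank correlation is used because expression
   moves monotonically but not linearly between subtypes; a convenient
   corollary is that any strictly increasing transform of the profile —
   a different normalization, a log base change — leaves calls
   unchanged.
4. **Decision tree.** Subtypes with rho strictly above the cutoff
   (default 0.1) are candidates. No candidate: the sample is
   **unstable** (UNS). One: a **single** call. Several: the top
   candidate is tested against each other candidate with the z test
   below; if every other candidate is significantly lower, the top
   subtype is predominant (single call); otherwise the call is **dual**
   and all candidates not significantly below the top are reported,
   ranked by decreasing rho.
5. **IM overlay.** Independently of the subtype, the sample is scored
   against the IM centroid (when one is supplied) with its own cutoff
   (default 0.1): IM-positive or IM-negative, so a call reads e.g.
   "BL1/IM-positive".

### The correlation-difference z test

The "z-score method" separating predominant from dual subtypes is
implemented as a Fisher z-transformation difference test adapted to rank
correlations:

$$ z = \frac{\operatorname{atanh}(\rho_a) - \operatorname{atanh}(\rho_b)}
           {\sqrt{2 \cdot 1.06/(n-3)}} $$

two-sided at `alpha = 0.05`, where $n$ is the number of genes both
correlations were computed over and the 1.06 factor is the Fieller
adjustment for the larger sampling variance of Spearman's coefficient.
At the published operating point this reproduces the reported behaviour:
a 0.27 vs 0.17 pair over a 101-gene signature gives $z \approx 0.72$,
not significant, hence a dual call. Because the two rhos share the same
sample profile they are not independent; a Steiger-style
dependent-correlation variant is available via
`classifier_config(tie_test = "steiger")`, taking the centroid-centroid
correlation as an extra argument. The independent-test default was
chosen because it is the simplest reading of a "z-score method", needs
no quantity beyond the two rhos and the gene count, and its decisions on
the packaged reference calls are consistent with all published dual
calls; the variant is a config switch so the sensitivity of a call to
this choice can be checked directly.

Numerical edge cases: $|\rho| = 1$ is clipped to $1 - 10^{-7}$ before
`atanh` (with a warning); exact rho ties at the top are kept in
alphabetical order for determinism and always produce a dual call, since
$z = 0$ is never significant; a zero-variance profile (e.g. a
single-sample batch centered to zeros) has no defined rank correlation
and is flagged and called UNS.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 0.1 | rho | published operating point shared by both TNBC algorithms |
| `alpha` | 0.05 | — | conventional two-sided level for the dual-vs-predominant test |
| `im_cutoff` | 0.1 | rho | kept equal to the subtype cutoff for consistency |
| `pseudocount` | 1.0 | linear expression | FPKM matrices contain zeros; log2(x+1) is the field's default |
| `centering_statistic` | mean | — | the common convention for centroid classifiers; median available |
| `max_missing` | 0.10 | fraction | strict >10% missing-gene refusal rule |

The centroid table is an *input contract*: centroids are expected on the
same centered log2 scale the classifier produces for samples. Whether
the original pipelines centered samples jointly with their centroids is
not recoverable from their description; treating centroids as
pre-centered is the one reading that keeps them reusable across cohorts,
and it is the one this package adopts.

## Signature reduction

`train_shrunken_centroids()` implements the standard
nearest-shrunken-centroids formulation: standardized class-mean
deviations $d_{ik} = (\bar x_{ik} - \bar x_i)/(m_k (s_i + s_0))$ with
pooled within-class standard deviation $s_i$, stabilizer $s_0$ the
median of the $s_i$, and $m_k = \sqrt{1/n_k - 1/n}$ (prior-free),
soft-thresholded by $\Delta$. At $\Delta = 0$ the shrunken centroids are
the raw class means exactly (the reconstruction is written as class mean
minus the clipped deviation, so this identity is bitwise).
`choose_delta()` picks $\Delta$ by stratified cross-validated
misclassification, breaking ties toward the larger threshold — the
smaller signature. Classification *inside* cross-validation uses the
shrunken-centroid discriminant; the exported reduced `centroid_set` is
deployed through the Spearman classifier. That hybrid is deliberate: it
mirrors how reduced TNBC signatures are in practice derived by shrinkage
but applied by correlation, and the package tests that reduced-signature
calls agree with full-signature calls on well-separated cohorts.

## Concordance and stability

`concordance_table()` matches on the *primary* subtype only by default
(concordance between classifiers is established on the
highest-correlation subtype); a lenient rule crediting either call's
dual list is available but off by default. UNS never matches anything —
not even another UNS sample, since two failures to classify are not
evidence of agreement. `stable_set()` calls a sample stable when its
primary subtype is identical and non-UNS in every condition where the
sample appears; conditions missing a sample are skipped rather than
disqualifying. The per-subtype breakdown is grouped by the reference
call set and is therefore reference-dependent; the overall match count
is symmetric.

The package ships the published call tables for the 17-cell-line TNBC
panel (two classifiers by two growth conditions, and the six stable
lines re-derived from five expression sources) as plain-TSV fixtures.
These fixtures carry only calls and their reported correlations: the
underlying expression data and the 2188- and 101-gene centroid tables
are external and proprietary, so published correlation values serve as
inputs here, not as quantities this package recomputes.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the classifier
assumes, with planted ground truth for recovery tests:

* each subtype owns a disjoint block of informative genes, elevated by
  `separation` (2.0 log2 units) in its centroid — disjoint blocks make
  planted truth unambiguous;
* single samples are centroid + Gaussian noise (`noise_sd`, 1.0 log2
  units); dual samples mix two centroids (`dual_mixing`, 0.5); unstable
  samples are pure noise; IM-positive samples add `im_effect` (2.0) on
  the IM block, which is disjoint from every subtype block, so the
  overlay is a modifier by construction and does not move subtype calls;
* profiles are exponentiated (`2^(x + 5)`, i.e. around 32 FPKM) to a
  linear scale so the pipeline's own log2 transform and centering are
  exercised, not bypassed;
* `apply_condition_shift()` adds one Gaussian per-gene offset
  (`batch_shift_sd`, 1.0 log2 units) shared by all samples of the
  shifted condition — the additive artifact per-batch centering removes
  exactly;
* every draw derives from one integer seed through per-sample streams,
  so cohorts are bit-reproducible and extending a cohort does not
  reshuffle earlier samples.

Default cohort sizes (10 single samples per subtype, 10% dual, 10%
unstable, 30% IM-positive, 500 genes with 20 informative per block) give
a 62-sample cohort on which the whole pipeline — generation,
preprocessing, classification, concordance — runs in well under a
minute; these sizes were chosen as typical of a cell-line panel study
and are used as-is by the test suite and the acceptance script.

What the generator does **not** emulate: count-level sampling noise,
transcript structure, tumor purity, stromal or mouse-read contamination,
or correlated gene-gene covariance. Gaussian log2-scale noise is the
simplest model consistent with a rank-correlation classifier; passing
recovery tests on these cohorts demonstrates the *procedure* is
implemented correctly, not that any particular real dataset would
classify stably.

## A worked example

```{r example}
spec <- synthetic_cohort_spec(seed = 7)
centroids <- generate_centroids(spec)
cohort <- generate_cohort(spec, centroids)
calls <- classify_cohort(cohort$matrix, centroids)
table(called = calls$status, planted = cohort$truth$truth_type)
```

```{r concordance}
panel <- tnbc_cell_line_calls()
concordance_table(panel$tnbctype_invitro, panel$tnbctypeim_invitro)
stable_set(panel)
```

## Known limitations

* Gene identifiers are matched as exact case-sensitive strings; symbol
  aliasing and ID translation are out of scope.
* The IM overlay is scored as a centroid correlation with its own
  cutoff. The original 101-gene pipeline determines IM with a separate,
  unpublished model; the overlay here is a documented stand-in with the
  same interface (positive/negative/undetermined).
* The published 2188- and 101-gene centroid value sets are not
  redistributed; users supply their own centroid tables, and the
  packaged call fixtures cover the analyses that depend on the published
  calls.
* No quantile normalization or cross-platform correction beyond
  per-batch gene centering is applied, matching the procedure the
  package implements.
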