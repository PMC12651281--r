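---
title: "Methods: multidimensional phenotype stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multidimensional phenotype stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenostrat)
```

## The model

`phenostrat` stratifies intellectual-disability cohorts on clinical severity
alone and asks, post hoc, whether genotype tracks the resulting strata. The
input is an ordinal score matrix: each patient is rated on 15 clinical
domains from 1 (mild or late-onset) to 4 (severe, neonatal-onset or
multisystemic), with a blank meaning the feature is absent, normal, or was
not assessed ("NA/Normal"). The pipeline treats these ordinal ratings as
numeric severity measurements — a deliberate simplification shared by most
multi-domain clinical severity scales — and proceeds in four steps:
per-domain Z-standardization, Euclidean hierarchical clustering of patients,
a k-group cut ranked by composite severity, and a gene-by-cluster Pearson
chi-squared test. A domain-by-domain Pearson correlation matrix describes the
internal architecture of the scoring system, and a CNV module profiles the
structural-variant arm of a cohort.

## Missing data: why NA defaults to zero

The rubric's NA level is not "value unknown" so much as "feature absent".
A patient without seizures has no seizure-severity score, and treating that
as missing-at-random would discard exactly the information that distinguishes
mild from severe multisystem disease. The default policy therefore encodes
NA as 0, extending each domain to an effective 0–4 scale where 0 means
"normal / not affected". The packaged cohort also makes the alternative
untenable in practice: some patients have as few as one recorded score, so
pairwise deletion would leave them without a usable profile. The
`na_policy = "drop"` switch keeps NAs (Z-scores are then computed over
observed values and correlations use pairwise-complete observations) for
sensitivity analyses; the clustering stage requires the complete `"zero"`
encoding.

One consequence is worth keeping in mind: with NA-as-zero, per-domain means
mix "absent" with "mild", so a domain's μ is a prevalence-weighted severity,
not a severity among affected patients. `cluster_profile()` deliberately
reports medians over the *observed* (1–4) scores, conditional on the feature
being present, which is the clinically interpretable summary.

## Normalization

`zscore()` uses the sample standard deviation (n − 1 divisor). Which divisor
is used is immaterial for everything downstream: switching to the population
SD rescales every column by the same factor √((n−1)/n), which rescales all
Euclidean distances uniformly and changes neither the merge order nor the
cluster assignment. Zero-variance domains cannot be standardized and map to
all-zero columns (observed cells only), so they contribute nothing to
distances rather than NaNs. A cohort of one patient is rejected: its SD is
undefined.

The per-patient **composite severity** is the unweighted mean of the
patient's domain Z-values. The aggregation rule is our design choice (a sum
would depend on how many domains a patient has observed under
`na_policy = "drop"`); it is used only to *rank* clusters, never as a test
statistic, so any monotone variant would give the same labels.

## Clustering

`hca()` implements bottom-up agglomeration over a pre-computed distance
matrix rather than delegating to `stats::hclust`, for one reason:
deterministic tie-breaking. Scored clinical cohorts routinely contain
patients with *identical* score rows (three siblings in the packaged cohort
share one profile), so zero and tied distances are the norm, not an edge
case, and `hclust`'s merge order under ties is an implementation detail.
When several cluster pairs share the minimal merge cost, `hca()` merges the
pair whose identifier — (smallest original member index, smallest index of
the other cluster) — is lexicographically smallest. This makes the merge
sequence, and hence the assignment, invariant to the order patients appear in
the file (a tested property). On tie-free data the heights agree with
`stats::hclust` to floating-point precision for both linkages (also tested,
alongside an exhaustive naive-agglomeration oracle).

Two linkages are first-class because both are defensible summaries of
inter-cluster distance on this kind of data and our upstream sources were
ambiguous between them: **complete** (default; merge cost = maximum pairwise
distance, robust to chaining on coarse ordinal profiles) and **ward**
(minimum within-cluster variance increase, in the Murtagh–Legendre form:
Lance–Williams on squared Euclidean distances with heights reported back on
the distance scale, i.e. `hclust`'s `ward.D2`). Every report names the
linkage used.

`cut_clusters()` cuts at the height giving exactly k groups (k defaults to 3
throughout the package interface; the choice of k is left to the analyst —
no gap statistic or silhouette machinery is implied) and renumbers groups by
descending median composite severity, so "cluster 1 = most severe" is stable
across platforms and input orderings rather than an artifact of dendrogram
orientation.

## The association test

`contingency()` counts patients per (gene, cluster) cell; `chisquare()`
computes the Pearson statistic without continuity correction and the upper
tail p-value at df = (r − 1)(c − 1). Two judgement calls:

* **Sparse tables are allowed.** An 18-gene × 3-cluster table over 29
  patients violates every expected-count rule of thumb. The function warns
  (expected counts < 5) but returns the statistic: this test is used here as
  a descriptive measure of non-random gene distribution, and the simulation
  module quantifies how the test actually behaves at this sparsity (see
  below). No Fisher/Monte-Carlo variant is provided because the single
  planned analysis is the Pearson test.
* **Empty rows or columns are dropped, with a warning, before df is
  computed** — the statistic is undefined at E = 0. df therefore reflects the
  realized table, which also makes df itself a useful check: the packaged
  cohort must give (18 − 1)(3 − 1) = 34 whenever no gene row is emptied.

On the packaged cohort the default pipeline yields X² = 53.97 (df = 34,
p ≈ 0.016); the reference analysis of this cohort reported X² = 54.566 with
the same df and p ≈ 0.014. The two values correspond to 3-group assignments
differing in the placement of at most a patient or two — at 29 patients the
statistic is sensitive at that granularity, and the original tooling's
tie-handling is not reproducible from the published description. Neither
linkage option reproduces 54.566 exactly (complete: 53.97; Ward: 58.00); we
report what the pipeline computes and treat the df identity and the
qualitative rejection of independence as the binding result.

## Correlation architecture

`domain_correlations()` reports Pearson R per domain pair with two-sided
p-values from t = R·√((n − 2)/(1 − R²)). p-values are reported unadjusted —
the single-matrix descriptive use here does not carry a formal
multiple-testing claim — but a Benjamini–Hochberg adjusted matrix is emitted
alongside, clearly labelled, for readers who want it. Heatmap ordering
(`order_heatmap()`) clusters domains on distance 1 − R rather than 1 − |R|:
sign matters, since positively and negatively correlated blocks should land
on opposite sides of the tree. NA correlations (zero-variance domains or
starved pairs) are imputed as distance 1 for ordering only, with a warning.

## CNV conventions

Coordinates are 1-based inclusive; lengths are `end − start`, which
reproduces the fixture's printed sizes at the 0.1 Mb reporting precision
(the ±1 bp convention difference is invisible at that rounding). Class
(P/LP/VUS, anything else → `unknown`) is kept per record; a patient's class
is the most severe among their records (P > LP > VUS). Origin is summarized
per *patient*: the carrier state (de novo, parental, uncertain) is a property
of the rearrangement event, so a patient whose single event produced both a
duplication and a deletion counts once.

## What the generator emulates — and what it does not

`generate_cohort()` draws, per patient: a latent cluster from the weights; a
real severity per domain from Normal(cluster profile mean, `domain_sd`),
rounded and clipped to 0–4, with 0 emitted as NA (structural missingness:
the feature is absent); additional NA masking at `na_prob` (recording gaps);
and a gene from the mixture (1 − s)·uniform + s·cluster-specific emission,
where s is `association_strength`. Defaults emulate the packaged cohort's
conditions: 29 patients, 3 clusters with weights proportional to the
observed 9/8/12 severity split, 18 gene symbols in three cluster-typical
blocks, `domain_sd = 0.5`, `na_prob = 0.1`, and severity profiles
(`default_domain_profiles()`) spaced 1.5 score units apart with a fixed
per-domain offset pattern (high onset/neuro/motor/ID loading, lower
systemic/skeletal loading).

Rounded-and-clipped Gaussians were chosen over an ordered-logit model because
the analysis itself treats scores numerically, and they keep the ground-truth
means directly interpretable on the 0–4 scale. The generator deliberately
does **not** emulate: rater subjectivity or inter-rater drift; family
structure (siblings with near-identical profiles, which the real cohort
contains and which produces the tied distances discussed above); informative
missingness beyond the structural score-0 rule; or any coupling between CNV
carriers and domain scores. Recovery results on synthetic cohorts therefore
validate the statistical machinery, not the clinical scoring process.

## Validation problem sizes

The test suite checks, among ~60 properties: exhaustive-oracle agreement of
the agglomeration on 100 random ≤10-point instances; brute-force agreement of
the chi-square on 100 random tables (1e−9); Z-column standardization to
1e−9; cluster recovery ARI ≥ 0.9 in ≥ 95% of 200 synthetic cohorts at the
reference separation (n = 300, k = 3, domain means 2 score units apart,
domain_sd = 0.5); and the pipeline-level chi-square type-I error at
`association_strength = 0` (n = 200, 1000 replicates), which lands at ≈ 0.04
against the nominal 0.05 — mild conservatism consistent with the sparse
18-gene table — and power ≈ 1 at s = 1. These sizes keep the full suite
comfortably under a coffee break on one core while leaving the Monte-Carlo
margins wide.

## Known limitations

* Ordinal scores are treated as interval-scaled; domains with skewed score
  usage weigh in through their Z-scale, not a latent-trait calibration.
* k is not selected from the data; the default k = 3 mirrors the reference
  analysis of the packaged cohort.
* The chi-square p-value on sparse tables is approximate (see above); treat
  it descriptively.
* The phenotype-overlap flags fixture is curated data, not a derived
  product: a handful of genes whose published category placements were
  mutually inconsistent were assigned to a single Venn region by editorial
  judgement (documented in `load_phenotype_flags()`).
* CNV profiling stops at interval arithmetic and bookkeeping; gene content
  and dosage-sensitivity annotation need external databases and are out of
  scope.
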