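# phenostrat

Multidimensional genotype–phenotype stratification for monogenic
intellectual-disability (ID) cohorts.

Clinical heterogeneity is the central obstacle to genotype–phenotype
correlation in ID: patients carrying variants in very different genes can
present overlapping symptoms, while carriers of the same gene vary in
severity. `phenostrat` implements a stratification pipeline for cohorts
scored on a 15-domain ordinal clinical severity rubric (onset, perinatal
history, vision, neurological signs, seizures, EEG, MRI, mental/behavioural,
motor development, intellectual disability, dysmorphism, skeletal,
accompanying anomalies, family history, syndromic presentation; each scored
1 = mild/late to 4 = severe/neonatal/multisystemic, blank = absent/normal):

1. **Normalization** — per-domain Z-scores, `Z_ij = (X_ij − μ_j) / σ_j`, so
   heterogeneous domains become comparable (mean 0, SD 1). Missing scores are
   encoded as 0 on an effective 0–4 severity scale (`na_policy = "zero"`), or
   kept missing (`"drop"`).
2. **Patient-level clustering** — agglomerative hierarchical clustering of
   patients on Euclidean distances between Z-profiles, with complete linkage
   (Ward available), a deterministic lexicographic tie-break, and a k-group
   cut relabelled by descending median composite severity (cluster 1 = most
   severe).
3. **Association** — gene×cluster (or pathway×cluster) contingency table and
   Pearson's chi-squared test of non-random gene distribution across the
   phenotype-derived clusters, `X² = Σ (O − E)² / E`,
   `df = (rows − 1)(cols − 1)`.
4. **Correlation architecture** — pairwise Pearson R between the 15 domains
   with t-based p-values and a clustered heatmap ordering on distance 1 − R.
5. **CNV profiling** — interval lengths from genomic coordinates, per-patient
   duplication/deletion categories, class and origin summaries.
6. **Simulation** — a synthetic-cohort generator with latent clusters,
   ordinal noise, structural and random missingness, and tunable gene–cluster
   association strength, providing ground truth for recovery and
   operating-characteristic checks.

Packaged fixtures under `inst/extdata/` carry a scored 29-patient monogenic
cohort (18 genes), a 13-record CNV table over 10 patients, a gene→pathway
map and curated gene-level phenotype flags.

## Worked example

```r
library(phenostrat)

res <- run_pipeline(
  phenostrat_example("cohort_monogenic.tsv"),
  cnv_file     = phenostrat_example("cnv_records.tsv"),
  pathway_file = phenostrat_example("gene_pathways.tsv"),
  outdir       = "results/run"
)

res$assignment
#> cluster assignment: k = 3 ( complete linkage ), sizes: 9/8/12

res$chisq
#> Pearson chi-squared: X2 = 53.972, df = 34, p = 0.01611 (n = 29)

res$cnv
#> CNV profile: 13 records in 10 patients
#> size range: 1.3 - 19.1 Mb
#> patient categories: dup_only=2, del_only=6, both=2

res$summary$max_r_neuro_motor_mental_id
#> [1] 0.7107966
```

Reading the output: the 29 patients split into three severity-ranked groups
of 9, 8 and 12 (cluster 1 collects the early-onset multisystem profiles —
among them the spastic-paraplegia families — cluster 3 the milder or focal
presentations). The 18×3 gene-by-cluster table rejects independence
(X² = 53.97 on 34 df, p ≈ 0.016): genes are not randomly distributed over
the phenotype-derived groups. The strongest domain correlation among the
neurocognitive block (neurological, motor, mental, ID) is R ≈ 0.71,
the coherent neurocognitive axis that drives the clustering. CNVs in the
companion cohort span 1.3–19.1 Mb; two patients carry duplications only, six
deletions only, and two both.

`run_pipeline()` also writes every intermediate artifact (Z-matrix, Newick
dendrogram, assignments, cluster profiles, chi-square JSON, correlation
matrices, CNV profile, summary JSON) to `outdir`; re-runs are byte-identical.

All steps are available as composable functions
(`load_cohort()`, `zscore()`, `hca()`, `cut_clusters()`, `contingency()`,
`chisquare()`, `domain_correlations()`, `cnv_summary()`,
`generate_cohort()`, `power_curve()`, ...); see the methods vignette
(`vignettes/phenostrat-methods.Rmd`) for the modelling choices.

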