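# lipostrat

Prognostic stratification of tumor expression cohorts by lipid-metabolic
gene programs.

## The problem

Clear cell renal cell carcinoma (ccRCC) tumors are strikingly lipid-rich,
and single lipid-metabolic genes carry prognostic information. `lipostrat`
operationalizes the cohort-level analysis behind that observation: patients
are clustered **only** on their expression of a biologically chosen gene set
(fatty acid degradation, elongation, synthesis, cholesterol biosynthesis —
alone or combined), and the resulting patient groups are then confronted
with survival. Because the grouping never sees the outcome, a survival
difference between clusters is evidence that the metabolic program itself
is prognostic.

The pipeline, per gene set:

1. Euclidean distances between patients over the set's genes;
2. average-linkage (UPGMA) hierarchical clustering, cut at a fixed 20
   clusters;
3. clusters holding ≥ 25% of the cohort are **dominant** (the rest are
   outlier splinters), numbered in decreasing order of overall survival
   (cluster 1 = best, by Kaplan–Meier restricted mean survival time);
4. stability of each dominant cluster scored by its mean silhouette width
   s(i) = (b − a)/max(a, b), computed among dominant-cluster samples only;
5. survival validation: log-rank test across dominant clusters and a Cox
   proportional-hazards model `h(t | x) = h₀(t)·exp(β₁·1[cluster 1] +
   β_T·T + β_N·N + β_M·M + β_age·age)` with one-hot TNM stage and linear
   age, so the cluster effect is adjusted for the clinical confounders.

Kaplan–Meier, log-rank and the Cox partial-likelihood Newton solver (Efron
tie correction) are implemented in-package from their defining formulas and
cross-checked against the `survival` package in the test suite. A
synthetic-cohort generator with survival-linked expression signal,
TNM/age confounding, censoring, and correlated lipid/immune tables makes
every stage testable without access to the original cohorts.

Intended users: computational biologists reproducing or extending gene-set
survival stratifications on bulk expression cohorts (TCGA-style matrices
plus clinical tables), and methodologists who want a tested, deterministic
reference implementation of the procedure.

## A worked example

```r
library(lipostrat)

co  <- simulate_cohort(cohort_config(seed = 7))   # n = 300, planted 2-group signal
run <- run_stratification(co$expr, co$clinical, co$sets, use_sets = "SIG")
print(run)
```

```
Stratification on gene set 'SIG' (30 genes, n = 300, cut at k = 20)
Outcome: stratified; dominant clusters: 2
# A tibble: 2 × 3
  cluster_number     n mean_silhouette
           <int> <int>           <dbl>
1              1   131           0.432
2              2   128           0.437
Log-rank across dominant clusters: chi-square = 42.91, p = 5.72e-11
Cox model (efron ties):
# A tibble: 7 × 8
  term        estimate hazard_ratio std.error statistic  p.value ...
1 T2            0.532         1.70    0.226        2.35 1.87e- 2
2 T3            0.878         2.41    0.147        5.98 2.20e- 9
3 T4            1.21          3.35    0.249        4.86 1.18e- 6
4 N1            0.518         1.68    0.152        3.41 6.52e- 4
5 M1            0.943         2.57    0.162        5.82 5.74e- 9
6 age           0.0218        1.02    0.00602      3.62 2.93e- 4
7 is_cluster1  -0.795         0.452   0.130       -6.13 8.55e-10
```

Reading the output: the fixed 20-cluster cut found two dominant clusters
(131 and 128 patients; the remaining 41 sit in minor outlier clusters) with
similar, clearly positive silhouette stability. Their survival differs
strongly (log-rank p ≈ 6e-11), and membership in the favorable cluster 1
roughly halves the hazard (HR 0.45) even after adjusting for TNM stage and
age — stage and age effects themselves come out in the expected direction.
The cohort was simulated with exactly this structure (group hazard ratio 3,
i.e. HR ≈ 0.33 for the favorable group), so the fit is recovering the
planted truth.

Cross-set comparison and plots:

```r
cmp <- compare_gene_set_runs(run_fad, run_chol, run_fad_chol)
cmp$venn           # which patients only the combined set calls favorable
autoplot(run)      # KM curves of the dominant clusters
tidy(run$cox)      # broom-style coefficient table
```

A thin CLI over the same functions ships in `inst/scripts/lipostrat`
(`simulate`, `cluster`, `run` subcommands).

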