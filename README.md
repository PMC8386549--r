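# iciscore

Immune cell infiltration (ICI) scoring and survival stratification for bulk
tumor expression cohorts.

Bulk tumor RNA-seq mixes malignant cells with infiltrating immune and
stromal cells, and the composition of that infiltrate is prognostic. For
researchers analyzing tumor cohorts (expression + clinical follow-up +
optional somatic mutations), `iciscore` implements the full workflow from
deconvolved immune-cell fractions to a prognostic per-patient score:

1. **Cell fractions** by linear nu-support-vector regression against a
   reference signature *S* (genes x cell types): for each standardized
   mixture column *y*, fit *y ~ S w* for nu in {0.25, 0.5, 0.75}, keep the
   minimum-RMSE fit, clamp *w* >= 0 and normalize to the simplex; a
   gene-permutation test (p = (1 + #{r_null >= r_obs}) / (n_perm + 1))
   screens unreliable fits. Rank-based immune/stromal enrichment scores
   complement the fractions.
2. **ICI clusters** (on fractions) and **gene clusters** (on DEG
   expression) by consensus K-means over subsamples, K chosen by consensus
   crispness (PAC) with paper-style overrides (K = 3 / K = 2).
3. **Differentially expressed genes** among ICI clusters by a moderated
   one-way F (empirical-Bayes variance shrinkage), called at
   |log2 FC| > 1 and FDR < 0.05.
4. **The ICI score**: DEGs split into type I / type II by correlation with
   the prognosis-anchored gene cluster, characteristic genes selected by a
   shadow-feature random forest, each type summarized by its first
   principal component score, and

   `ICI score = S_PCA I − S_PCA II`
5. **Survival stratification** at the maximally selected log-rank cutpoint
   (follow-up < 30 days excluded), Kaplan-Meier curves and log-rank tests.
6. **Tumor mutation burden**: nonsynonymous mutation counts from MAF-like
   tables, TMB x ICI subgroups, Spearman association, and per-gene Fisher
   tests of mutation frequency between ICI-score groups.

A seeded synthetic-cohort generator (`simulate_cohort()`) produces
expression, clinical, and mutation inputs with known ground truth
(fractions, clusters, DEG signs, latent immune score, mutation counts), so
the whole pipeline is testable without any data download.

## Worked example

```r
library(iciscore)

cfg <- simulation_config(n_genes = 300, n_samples = 120, n_cell_types = 6,
                         n_clusters = 3, deg_fraction = 0.15, seed = 14)
sim <- simulate_cohort(cfg)

fit <- ici_fit(sim$expression, sim$clinical, sim$reference,
               mutations = sim$mutations, ici_k = 3, reps = 60, seed = 14)
summary(fit)
```

```
Immune cell infiltration scoring fit
  samples: 120   ICI clusters: 3   gene clusters: 2
  DEGs: 105   signature genes: 24 type I, 29 type II
  ICI score cutpoint: 4.653   high: 55   low: 65
  high vs low log-rank: chi2 = 64.60, p = 9.17e-16
  median OS (days): high = 4532.1, low = 258.5
  TMB vs ICI score: Spearman rho = -0.033, p = 0.717
```

Reading the output: the cohort splits into 3 immunophenotypes; 105 genes
are differentially expressed among them (planted signature genes plus
cell-type markers, which genuinely differ between immunophenotypes), of
which 24 type I and 29 type II survive the selection step and form the two
signature scores. Each patient's ICI score (type I minus type II PC1
coordinate) is cut at its optimal survival cutpoint: the 55 high-ICI
patients live substantially longer than the 65 low-ICI patients (median
4532 vs 259 days, log-rank p ~ 9e-16), while TMB is uncorrelated with the
score (rho ~ 0) — the two axes carry independent information. `plot(fit)`
draws the two Kaplan-Meier curves and `predict(fit, new_expression)`
scores new samples with the fitted signature and cutpoint.

Per-stage functions (`deconvolve()`, `consensus_cluster()`,
`moderated_anova()`, `boruta_select()`, `pca_signature_score()`,
`maxstat_cutpoint()`, `compute_tmb()`, ...) expose every intermediate
result; see the methods vignette (`vignettes/ici-scoring-methods.Rmd`) for
models, defaults, and design rationale.

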