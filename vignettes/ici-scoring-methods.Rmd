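---
title: "Immune cell infiltration scoring: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune cell infiltration scoring: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk tumor expression profiles mix malignant cells with infiltrating immune
and stromal cells. The composition of that infiltrate carries prognostic
information: immune-rich ("hot") tumors often behave differently from
immune-poor ("cold") ones. This package implements a complete workflow that
turns a gene-by-sample expression matrix, a clinical table, and optionally
a somatic mutation table into (i) per-sample immune-cell fractions,
(ii) reproducible immunophenotype clusters, (iii) a one-dimensional
**ICI score** summarizing each tumor's immune configuration, and (iv) a
prognostic high/low stratification of that score, with tumor mutation
burden (TMB) analyses on the side.

The pipeline, exposed as `ici_fit()` and as per-stage functions, is:

1. **Deconvolution.** For each sample, cell-type fractions are estimated by
   linear nu-support-vector regression (nu-SVR) of the standardized mixture
   on a standardized reference signature (genes x cell types). The signature
   matrix is standardized by its global mean and standard deviation and each
   mixture column by its own; nu is scanned over {0.25, 0.5, 0.75} and the
   fit minimizing the reconstruction RMSE wins; negative coefficients are
   clamped to zero and the rest normalized to the simplex. A permutation
   test (gene-label shuffling of the mixture column, add-one estimator
   `p = (1 + #{r_null >= r_obs}) / (n_perm + 1)`) screens samples whose fit
   is indistinguishable from noise at p >= 0.05; they are flagged rather
   than dropped so downstream joins stay total. Rank-based single-sample
   enrichment scores (weight exponent 0.25 on absolute ranks) provide
   immune/stromal summaries per sample.
2. **Immunophenotyping.** Consensus K-means over 100 subsampling rounds
   (80% of samples per round) on the cell fractions defines ICI clusters;
   the same machinery on z-scored expression of differentially expressed
   genes (DEGs) defines gene clusters. Cluster letters are anchored to
   prognosis: "A" is the cluster with the best median Kaplan-Meier
   survival.
3. **Differential expression.** A moderated one-way F across ICI clusters:
   per-gene residual variances are shrunk toward a scaled
   inverse-chi-square prior fitted by matching the first two moments of
   `log s^2` (the trigamma inversion is a small Newton solve). A gene is a
   DEG when its largest absolute pairwise group-mean difference exceeds
   1 log2 unit and its Benjamini-Hochberg FDR is below 0.05.
4. **Signature construction.** DEGs positively Spearman-correlated with the
   indicator of gene cluster A are **type I**, the rest **type II**.
   Characteristic genes are selected by a shadow-feature random-forest
   procedure (below). Each type's score, `S_PCA I` and `S_PCA II`, is the
   per-sample coordinate on the first principal component of the z-scored
   type submatrix, oriented so high score means high signature expression.
   The ICI score is `S_PCA I - S_PCA II`.
5. **Survival stratification.** After excluding follow-up shorter than 30
   days, the optimal cutpoint maximizes the absolute standardized two-group
   log-rank statistic over midpoints between consecutive distinct scores
   whose groups both hold at least 10% of samples.
6. **Mutation integration.** TMB is the raw count of nonsynonymous MAF
   records per sample (no per-megabase normalization — no capture size is
   assumed); the default high/low split is at the median. TMB and ICI
   groups cross into four subgroups; their association is a Spearman
   correlation; per-gene frequency differences between ICI groups use
   two-sided Fisher exact tests with BH correction.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| nu grid | 0.25, 0.5, 0.75 | the published SVR-deconvolution convention; RMSE picks the winner |
| `n_perm` | 1000 (screen), 0 in `ici_fit` | classical screen size; the screen is optional because it dominates runtime on large cohorts |
| screen threshold | p < 0.05 | conventional significance of the fit correlation |
| enrichment exponent | 0.25 | the published single-sample enrichment default |
| `k_max` | 9 | widest K examined by the consensus scan |
| `reps`, `p_item` | 100, 0.8 | consensus-clustering defaults; all features kept per round |
| DEG thresholds | \|log2FC\| > 1, FDR < 0.05 | the usual dual criterion; log2fc is the max pairwise group-mean difference so it is defined for any K |
| Boruta | 200 trees, 100 iterations, alpha 0.01 | forest size and decision confidence of the selection loop |
| `minprop` | 0.1 | conventional admissibility bound of maximally selected statistics |
| `min_followup` | 30 days | removes perioperative deaths from survival contrasts |
| TMB split | median | yields near-even groups; a maxstat split is available |

All downstream statistics operate on `log2(TPM + 1)`; the pseudocount of 1
keeps zeros at zero, and fold-change thresholds are only meaningful on the
log scale. Cohorts are merged on TPM (gene intersection, sample union, no
batch correction — the cohort label is carried instead) and transformed
once.

# Choosing K: why PAC rather than the delta-area argmax

The classical delta-area series reports, per K, the relative change in area
under the consensus CDF. We compute and report it, but do not use its argmax
to choose K: for a crisp planted K*-partition the area at K = 2 equals one
minus the co-clustering mass, which lands arithmetically on the same value
as the relative gain at K* (for three equal clusters, 4/9 versus a crossover
at 0.4457), so the argmax flips with subsampling noise. Instead the chooser
uses the proportion of ambiguous clustering (PAC: consensus entries strictly
between 0.1 and 0.9). Reproducible structure drives PAC to essentially zero
at the true K — and at coarser merges of it when two groups are
preferentially mergeable — so the chooser returns the **largest K tied at
the minimal PAC** (within 0.01, and at or below the crispness bound 0.05),
i.e. the finest reproducible partition. The near-minimum tie window matters:
forced over-splits of truly coarser structure can be marginally crisp
(PAC 0.03-0.05) but sit visibly above the exact-zero minimum that genuine
structure attains. Structureless data are never crisp at any K and fall
back to the smallest K examined. The chosen K
can always be overridden (`ici_k`, `gene_k`), mirroring analyses that fix
K = 3 immunophenotypes and K = 2 gene clusters.

# The shadow-feature selection loop

Each iteration appends a shuffled "shadow" copy of every candidate gene,
fits a `ranger` random forest (permutation importance, fixed seed, one
thread), and scores a hit for each undecided gene whose importance exceeds
the maximum shadow importance. Two-sided binomial tests on the hit counts
(Bonferroni-corrected at alpha over the current candidates) confirm genes
persistently above half hits and reject those persistently below. One
deliberate departure from the common convention: shadows are shuffles of
**all** original candidates, not only the undecided ones. A shadow pool that
shrinks as genes are rejected weakens the max-shadow reference exactly when
the surviving, most chance-associated genes need the strongest null, and
measurably lets pure-noise genes reach confirmation; the full pool keeps the
reference at constant extreme-value strength. Note the residual caveat: a
noise gene whose in-sample association happens to be extreme is a *real*
association in that dataset, and an all-relevant procedure can legitimately
confirm it on rare occasions.

# The synthetic cohort generator

`simulate_cohort()` produces every input with known ground truth:

* **Expression** is `reference %*% t(fractions)` per sample (nonnegative
  mixture of cell-type profiles), scaled by a log-normal library-size
  factor, shifted on the log2 scale by cluster-specific DEG effects, and
  multiplied by log-normal noise (`noise_sd` on the log2 scale).
  Multiplicative noise matches RNA-seq heteroskedasticity and keeps values
  nonnegative.
* **The reference** gives each cell type a disjoint block of 8-fold
  elevated marker genes over a shared log-normal baseline.
* **Planted clusters** are Dirichlet draws (concentration 100) around
  archetypes that each elevate their own disjoint block of cell types.
  Equidistant block archetypes — rather than archetypes along a
  compositional gradient — are deliberate: compositionally close cluster
  pairs create genuinely crisp coarse merges that make the planted K
  ambiguous even to an ideal chooser, which would test the chooser's
  tie-break rather than the pipeline.
* **The latent immune score** is the mean z-expression of positive-sign
  DEGs minus that of negative-sign DEGs, computed from the realized data;
  it deliberately mirrors the ICI score's type-I-minus-type-II structure so
  parameter-recovery tests are meaningful. DEG shifts scale with a linear
  0..1 infiltration grade across clusters.
* **Survival** is exponential with log-hazard `-hazard_beta * latent_score`
  around a baseline rate of 1/1000 per day: a *positive* `hazard_beta`
  makes immune-rich samples live longer, the direction reported for
  immune-hot tumors, so recovery tests can assert that the high-ICI group
  has better outcome. With probability `censor_rate` a sample is censored
  uniformly within its event time.
* **Mutations** are per-sample Poisson counts (means uniform in
  `mutation_rate_range`) expanded into MAF-like records over a Zipf-skewed
  60-gene pool, roughly 70% nonsynonymous, which exercises the TMB class
  filter.

What the generator does **not** emulate: batch effects between merged
cohorts, copy-number or methylation structure, gene-gene co-expression
beyond the mixture itself, overlap between DEGs and cell-type markers
(DEG positions avoid marker blocks when possible), or non-proportional
hazards. Passing recovery tests on these cohorts therefore shows the
pipeline's internal consistency, not robustness to those real-data
complications.

# Numerical and convention details

* Deconvolution is invariant to positive rescaling of a raw mixture column
  (standardization absorbs scale); fractions sum to one within 1e-9.
* The permutation p-value uses the add-one estimator and can never be zero.
* Zero-variance genes never produce a zero denominator in the moderated F
  (the shrunken posterior variance is bounded away from zero); a
  `prior_df` override exposes the unshrunk ordinary F (`prior_df = 0`) and
  the fully shrunk common-variance limit (`prior_df = Inf`).
* Rank tests use midranks with the standard tie correction; censored
  observations tied with an event time remain at risk at that time.
* Cutpoint candidates are midpoints between distinct values, so group
  assignment at the boundary is unambiguous; the selected cutpoint is used
  for grouping and downstream log-rank p-values are reported without
  selection correction — an acknowledged inferential caveat.
* PC1's sign is not identifiable; the positive-orientation rule ties high
  scores to high signature expression.
* Gene typing uses Spearman correlation (robust to the unknown expression
  scale); a constant gene has undefined correlation and falls to type II
  with a warning.
* All randomness flows through explicit integer seeds; consensus
  subsampling is tied to sorted sample ids, so partitions are invariant to
  input row order.

# Problem sizes in the test-suite simulations

The packaged simulations use cohorts of 50-300 samples, 60-2000 genes and
3-8 cell types: deconvolution recovery at 50 samples x 8 types
(noise_sd 0.2), screen calibration over 200 pure-noise samples at 200
permutations, consensus recovery at 120 samples, differential-expression
calibration at 2000 genes x 60 samples over 20 replicates, selection
studies at 100 genes x 200 samples, and the end-to-end recovery at 300
samples. These sizes give stable Monte-Carlo behavior for the asserted
tolerances while keeping the default test run short.

# Known limitations

* The workflow assumes the reference signature's cell types span the
  mixture; unmodeled cell types are absorbed into the fitted fractions.
* With `ici_k = NULL` the chosen K is data-driven and need not equal a
  fixed three-cluster convention on real cohorts; both paths are
  first-class.
* The ICI score's scale is cohort-relative (z-scores and PCA are fitted on
  the cohort), so scores from different fits are not directly comparable;
  `predict()` projects new samples onto a fitted signature instead.
* Fisher tests of per-gene mutation frequencies ignore mutual exclusivity
  and covariates; they are the tabular analogue of a waterfall-plot
  comparison, not a driver-discovery method.
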