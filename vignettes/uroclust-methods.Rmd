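---
title: "Models and methods behind uroclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uroclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

uroclust implements a three-cluster molecular classification framework for
urothelial carcinoma (UC) and the statistics used to characterise those
clusters across bulk transcriptome and proteome cohorts. This vignette
explains the models, the tunable parameters, and the design choices made
where the methodology left the details open.

## The two-step cluster definition

Molecular clusters are defined on a training cohort in two steps.

**Step 1 — metagenes.** The whole transcriptome (each gene standardised to
mean 0, SD 1 across samples) is quantised onto a toroidal 16 x 16
self-organising map (SOM) by squared Euclidean distance, giving up to 256
*metagenes*: micro-clusters of tightly co-regulated genes, one per SOM node.
`train_som()` uses batch training: each epoch assigns every gene to its
best-matching unit (BMU) and moves each codebook vector toward the
neighbourhood-weighted gene mean, with a Gaussian kernel over the wrapped
grid distance. Batch training was chosen over online training because it is
deterministic given a seed (the codebook is initialised by sampling genes)
and vectorises well. Defaults: 100 epochs, learning rate 0.5 decaying
linearly to 0.005, radius starting at half the larger grid dimension and
decaying linearly to 1; a start radius at or below 1 stays constant. These
schedules are this package's choices; the quality metrics, not the training
trajectory, are the contract.

Three QC metrics (`som_quality()`) support hyperparameter choice on a 75/25
gene split: explained clustering variance
(1 − Σ‖x − codebook(BMU)‖² / Σ‖x − x̄‖², defined as 1 when total variance is
zero), topology error (fraction of genes whose first and second BMUs are not
wrapped-grid neighbours), and neighbourhood preservation (mean Spearman
correlation between feature-space distances and BMU grid distances to a
seeded 100-gene probe subset — one of several reasonable formulations; this
one is fixed here).

A note on monitoring: with an active neighbourhood kernel, early epochs
*smooth* the codebook, which can temporarily raise the quantisation error
while improving topology. The per-epoch error trace is therefore monotone
only in the vanishing-neighbourhood regime (radius below 1 with a bubble
kernel, where the update is exactly a k-means step); the test suite asserts
monotonicity there and treats the general trace as diagnostic output.

**Step 2 — regularised clustering.** Samples are scored per metagene by
single-sample gene-set enrichment (ssGSEA, below) and clustered by
hard-threshold regularised k-means (`fit_htkmeans()`). This is Lloyd k-means
plus per-feature feature selection: after each assignment/update round, any
feature whose between-cluster sum of squares is at most `lambda * n` is
*deactivated* — its centroid entries collapse to the global feature mean and
it stops contributing to assignments; features whose separation grows again
may re-enter. The penalised objective is

    sum_{j active} WCSS_j + sum_{j inactive} TSS_j + lambda * n * #active .

The inactive features must contribute their total sum of squares for the
threshold rule to be a coordinate-descent step on the objective (otherwise
deactivation would always look free); with that term every step — assignment,
mean update, thresholding — is monotone, `lambda = 0` is exactly Lloyd
k-means, and the active set is nested in lambda for fixed assignments.
Restarts use k-means++ seeding (`n_init = 50` by default for final fits).
`tune_htkmeans()` ranks (k, lambda) candidates by the summed rank of mean
silhouette, explained variance, neighbourhood preservation and five-fold
cross-validated label stability; rank-sum aggregation is this package's
choice of how to "compare" the criteria.

## ssGSEA scoring

`ssgsea_scores()` ranks features within each sample (descending, average
ranks for ties) and walks down the ranked list accumulating the difference
between the weighted in-set empirical CDF — a feature at absolute rank r from
the top carries weight r^alpha, alpha = 0.25 — and the unweighted out-of-set
ECDF; the set score is the sum of those differences, and all scores are
divided by the overall score-matrix range. Because only within-sample ranks
matter, scores are invariant to any strictly monotone per-sample transform,
which is what makes them comparable across platforms. Scores are computed
per cohort, after cross-cohort batch adjustment.

## Label transfer

Validation transcriptome cohorts are assigned by an inverse distance-weighted
k-nearest-neighbour classifier (`knn_assign()`): among the k = 7 nearest
training samples, each cluster scores the summed inverse distances of its
neighbours; a zero-distance neighbour short-circuits. k is not dictated by
the methodology; 7 is the default and exposed. In `run_pipeline()` the
k-NN operates on the HTK-active metagene subspace: the hard threshold exists
precisely to identify the discriminative metagenes, and inactive metagenes
carry no cluster signal, only noise. At the pipeline's default shrinkage
(lambda = 0.1) the active set on the default synthetic study (~80 of 240
scorable metagenes) matches the number of informative modules the generator
plants, which is why that value is the default operating point.

Proteomes and cell lines, which share only part of the transcriptome's
feature space, are assigned by multinomial elastic-net classifiers
(`fit_enet()`, glmnet-backed) trained on the features shared with the
training cohort; (alpha, lambda) are chosen by cross-validated multinomial
deviance with stratified folds. Queries missing up to half the model's
features are imputed at zero after scaling and flagged; samples whose
maximum class probability falls below 0.5 are flagged unreliable (the
reliability cut-off is exposed).

## Cluster characterisation

**Differential regulation** (`diff_features()`) uses a composite rule per
cohort: one-way ANOVA across clusters with eta-squared
(SS_between/SS_total), post-hoc one-sample T-tests of each cluster against
the fixed cohort grand mean, and Benjamini-Hochberg FDR applied separately
to the ANOVA and T-test families. A (feature, cluster) pair is called at
q_ANOVA < .05, eta2 >= .06 and q_T < .05. Features shared by at least
`min_cohorts` cohorts (`shared_features()`, optionally sign-consistent —
an added guard, toggleable) are pooled by DerSimonian-Laird random-effects
meta-analysis (`dl_meta()`), the standard method-of-moments estimator of
between-study variance.

**Mutation enrichment** (`permutation_enrichment()`) compares a gene's
weighted mutation frequency in a cluster with a cohort-stratified label
permutation null (cluster sizes preserved within each cohort), with add-one
corrected one-sided p-values and BH FDR across (gene, cluster) pairs.
The "weighted" scheme is read as per-sample weights (default 1) inside
cohort strata; the original tooling's internals are not published, so this
contract is fixed here. Note that with `n_perm` permutations the smallest
attainable p is 1/(n_perm + 1); detecting planted signals *after* FDR
correction across many pairs needs n_perm in the thousands.

**Networks** (`correlation_network()`, `jaccard_network()`,
`leiden_communities()`): Spearman co-regulation networks (edges at
rho >= .5 or .3 — the threshold is a required argument, deliberately without
a default) and Jaccard signature-similarity networks (J >= .3), partitioned
by weighted-modularity Leiden (igraph). Closed bounds: an edge exactly at
the threshold is kept.

**Metabolism** (`reaction_activity()`): boolean gene-protein-reaction rules
are evaluated in a Monte-Carlo simulation — each draw samples every gene's
log2 fold change from Normal(estimate, SE), converts to linear fold change,
and evaluates AND as the minimum (scarcest complex member) and OR as the sum
(additive isozymes) of operand values, normalised by the all-ones baseline
so every rule is exactly 1 under zero differential expression. The min/sum
convention is this package's fixed reading of rule semantics the source
tooling does not print; it is monotone (raising any gene never lowers any
reaction) and baseline-correct by construction. Reactions are `activated` /
`inhibited` when the central 95% interval of draws clears 1. Subsystem
enrichment compares each subsystem's significant-reaction count with 10 000
uniform draws from the reaction pool; flags need FDR q < .05 and odds ratio
>= 1.44.

**Screens**: `chronos_bootstrap()` resamples cell lines within cluster
(percentile CIs, 2000 replicates; BCa was not needed at these sample sizes)
and flags knockout effects with mean sign-flipped Chronos score above 0.5.
`ridge_train()` / `ridge_predict()` use the closed-form ridge solution with
cross-validated lambda and report within-cohort Z-scores, oriented so higher
Z means more resistant.

**Clinical statistics** (`cramers_v()`, `mw_effect()`, `peto_peto()`,
`km_quantiles()`, `cox_univariable()`): chi-square *without* continuity
correction — the published effect sizes only reproduce uncorrected — with
Cramer's V; tie-corrected Mann-Whitney with r = |Z|/sqrt(n); a hand-rolled
k-group weighted log-rank whose Peto-Peto weights are the left-continuous
pooled survival estimate (unit weights recover the plain log-rank exactly,
which is the cross-check against `survival::survdiff`); Kaplan-Meier
quantiles under the first-crossing convention (the q-survival quantile is
the first time S(t) <= q, so the "25% quantile" is when 75% have died), with
Greenwood-band CIs; and Cox fits delegated to `survival::coxph`.

## The synthetic multi-cohort generator

Real inputs are large public cohorts; the generator (`simulate_multicohort()`)
emulates their statistical structure so the pipeline is testable without
downloads. Genes belong to co-regulated modules; expression is
`baseline + archetype[cluster, module] + batch(cohort, gene) + noise` on the
log2 scale. Defaults — fixed once, as the package's study conditions — are:

* 3 cohorts x 100 samples, 2000 genes in 200 equal modules;
* cluster prevalences (30, 24, 46)% — the pooled-collective proportions;
* archetype shifts of 2 log2 units in exactly one cluster for 30% of
  modules (cycling through +/− single-cluster patterns), the remaining
  modules carrying no cluster signal so feature selection has something to
  discard;
* gene baselines Normal(8, 2) log2 units, residual noise SD 1 (a realistic
  within-group log2 spread for array/RNA-seq data), additive per-(cohort,
  gene) batch offsets with SD 0.5; multiplicative batch effects are omitted
  because per-cohort standardisation removes them anyway;
* cluster hazard ratios (1.8, 1.5, 1) for the survival companion;
* a proteome companion covering 30% of genes with 1.5x noise, emulating the
  narrower, noisier coverage of proteome cohorts.

What the generator deliberately does not emulate: non-Gaussian expression
distributions, correlated noise within samples, platform-specific
missingness, copy-number or fusion events, and single-cell structure.
Passing recovery tests therefore demonstrates the pipeline's internal
consistency at realistic effect sizes, not performance on real data.

`batch_adjust()`'s default `center_scale` method z-scores each shared
feature within each cohort and restores the pooled mean/SD; population
(1/n) variances are used throughout so the adjustment is exactly idempotent.
ComBat is available as an optional delegate when the sva package is
installed.

## Numerical conventions

Ties break to the lowest index everywhere (BMU assignment, cluster
assignment, k-NN class ties). Zero-variance features are dropped with a
message where a statistic is undefined (ANOVA, correlation networks) or
scored at the null value where a convention exists (AUC = 0.5). Every
stochastic stage consumes a seed derived as a pure function of the global
seed and the stage name (`stage_seed()`), so changing one stage's
parameters never perturbs another stage's randomness, and fixed seeds
reproduce results bit for bit.

## Problem sizes used in the test suite

The recovery tests run the full pipeline on the default 3 x 100-sample
configuration (about 15 s per seed on a laptop-class core) over five seeds;
oracle-equivalence and null-calibration suites use small instances (tens of
samples, hundreds of permutations) sized so the whole suite completes in a
few minutes. These sizes are the package's own test design.

## Known limitations

* The published operating point (k = 3) is reproduced, but the published
  shrinkage value and tuning curves are not available; only the tuning
  procedure is.
* Whether the original metagene scores used GSVA's default kernel or its
  ssGSEA mode is ambiguous in the source; the ssGSEA reading is implemented,
  with the exponent exposed.
* Gene identifiers are matched by exact string equality; no symbol aliasing.
* The GPR rule-evaluation semantics (min/sum) and the permutation-weighting
  scheme are fixed stand-ins for unpublished internals, as noted above.
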