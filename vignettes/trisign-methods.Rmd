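---
title: "Methods: miRNA/mRNA signatures across normal, tumor and metastasis tissue"
author: "trisign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA/mRNA signatures across normal, tumor and metastasis tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisign)
```

# Overview

`trisign` implements an integrated analysis of nCounter-style miRNA and
mRNA count profiles over three tissue classes — adjacent normal breast,
primary triple-negative breast cancer (TNBC), and regional lymph-node
metastasis — together with patient survival. The chain is: detection and
variability filtering with normalization; per-feature linear models over
the three pairwise tissue contrasts with empirical-Bayes moderation,
Benjamini–Hochberg correction and Venn partitioning; permutation-validated
Cox proportional-hazards miRNA signatures with risk-score classification,
Kaplan–Meier curves and log-rank comparisons; target-prediction-filtered
miRNA∶mRNA anti-correlation; and Spearman-distance average-linkage
clustering with correlation-threshold tree cutting.

Every stage is exercised against a synthetic cohort generator
(`simulate_cohort()`) whose planted effects are known, so recovery,
calibration and oracle-equivalence properties can be tested without any
patient data. This vignette records the models, the tunable parameters,
and the design decisions taken where the analysis recipe left genuine
choices open.

# The synthetic cohort generator

`simulation_config()` describes a cohort; `simulate_cohort()` realizes it
deterministically from a seed (identical config + seed is bit-identical).

**Expression.** Per-probe baseline log2 means are uniform on
`baseline_log2_range` (default 4–10, a typical nCounter endogenous-probe
dynamic range). Planted log2 fold changes shift class means with the sign
convention *second class minus first* over the ordering normal < tumor <
mets; a `N_vs_T` shift is treated as a tumor-lineage effect and carried
into the metastasis class unless a `T_vs_M` entry says otherwise, so the
three comparisons compose additively. Gaussian noise (`noise_sd`, default
0.5 log2 units) is added per sample and counts are `round(2^x)`. The
count model is log2-normal because the downstream analysis is entirely on
the log scale; no published count distribution was available to emulate.
Negative controls are Poisson with mean 5 — a stated assumption, not an
inference from data.

**Cohort layout.** Defaults mirror the study conditions: 59 normal, 165
tumor and 54 metastasis samples with 55 matched normal/tumor pairs.
Matched pairs share a patient id and a patient-level random intercept
(SD 0.3 log2 units) so matched analyses have something to gain. Age and
ordinal tumor grade are drawn independently of expression.

**Survival.** Tumor samples receive overall survival (OS) and
distant-disease-free survival (DDFS) times from an exponential
proportional-hazards model, hazard `h0 * exp(sum(beta_i * x_i))` with
`x_i` true log2 expression, so `exp(beta)` is the hazard ratio per
2-fold expression change. The two endpoints are independent draws from
the same hazard specification; distinct per-endpoint effects can be
produced by two generator calls. Censoring is independent uniform on
`[0, T_max]`, with `T_max` solved by `uniroot` so the expected censored
fraction matches the configured value (default 20%); a zero fraction
disables censoring entirely.

**miRNA∶mRNA pairs.** A planted pair rewrites the gene's log2 profile as
`baseline + slope * (x_miRNA - mean) + noise`, so the implied Pearson
correlation is `slope * sd(x) / sqrt(slope^2 sd(x)^2 + noise_sd^2)`.
`generate_target_predictions()` emits the planted pairs plus seeded decoy
pairs with no planted association.

**What the generator does not emulate:** batch or cartridge effects,
probe-specific hybridization biases, count overdispersion beyond the
log-normal noise, correlated survival endpoints, and
expression-confounded covariates (a confounded mode is out of scope).
Passing recovery tests therefore show that the estimators are correct
under the assumed data-generating model, not that the pipeline is robust
to every artifact of real nCounter data.

# Preprocessing

The stage order is fixed: manufacturer correction factors (multiplicative
on counts; default 1 since the published values are unavailable), then
`log2(count + 1)` (the pseudocount keeps zero counts finite), then
filtering, then normalization.

- **Detection threshold** (`detection_threshold()`): per sample, the mean
  of the negative-control values plus twice their sample SD (n−1
  denominator), computed on the log2 scale — the same scale as the
  filtered matrix. Whether the original analysis thresholded raw or log
  counts is unstated; the log scale is used here because the filter is
  applied to the log matrix, and the choice is visible in the code.
- **Filtering** (`filter_features()`): a feature is dropped when it is
  below the per-sample threshold in at least half of the samples
  (`min_below_frac = 0.5`, boundary inclusive: 2 of 4 samples removes),
  or when its IQR across samples is below 0.5 log2 units (boundary
  exclusive: IQR exactly 0.5 is kept). Both rules are reported per
  removed feature. Filtering precedes normalization so undetected probes
  cannot contaminate the reference quantiles. An empty result is an
  error, never a silent success.
- **Quantile normalization** (`quantile_normalize()`): every column is
  forced to the across-column mean of sorted columns; tied values receive
  the mean of the reference values at their tied ranks, making the output
  invariant to tie order. The transform is idempotent on tie-free input.
- **Invariant-set normalization** (`normalize_to_invariants()`): per
  sample, the deviation of the invariant probes' mean from their grand
  mean is subtracted. The invariant probe list is a user input.

**A known limitation of quantile normalization, and a design decision.**
Quantile normalization equalizes the entire column distributions. If a
single probe is shifted far enough that its values exceed the global
intensity maximum of the unshifted classes, its fold change is compressed
toward the across-class average of the extreme order statistics; we
measured roughly 2 log2 units of compression for a lone +5.35 shift among
150 null probes. Real cohorts, with hundreds of bidirectionally
deregulated probes over a wide dynamic range, are far less exposed, but
the planted-recovery analyses in this package use the invariant-set path
(with the unplanted probes as the invariant set), which is exact for
per-sample offsets. Both normalization strategies are part of the
original processing description.

# Differential expression

`run_diffexpr()` fits per-feature ordinary least squares on a group-means
design (class indicators; optional patient blocks for matched analyses),
estimates the pairwise contrasts `N_vs_T = tumor − normal`,
`N_vs_M = mets − normal`, `T_vs_M = mets − tumor` (so a miRNA
up-regulated in tumor has positive `N_vs_T` logFC), moderates the
residual variances, and adjusts P values within each comparison.

**Empirical-Bayes moderation** (`ebayes_moderate()`) is implemented
directly rather than delegated: assuming `s2_g ~ s02 * F(d_g, d0)`, the
prior df `d0` and prior variance `s02` are estimated by method of moments
on `log(s2_g)` (mean and variance of the log-F distribution, with a
Newton inversion of the trigamma function), and the posterior variance is
`(d0*s02 + d_g*s2_g) / (d0 + d_g)`. Moderated t uses `d0 + d_g` df. Two
limits are honored exactly: `d0 = 0` reproduces the ordinary t-statistic,
and under-dispersed log-variances give `d0 = Inf` with every posterior
variance equal to `s02` (not a crash). The estimates agree with
`limma::squeezeVar` to 1e-6 in the test suite, which serves as an
independent cross-check only.

**Significance.** DE calls use strict `P < alpha` (default 0.05) on raw P
values, with BH-adjusted values always reported alongside; the original
description is ambiguous about which scale the 0.05 rule used, so the
choice is a config switch with raw as the documented default.
`venn_partition()` splits the three call sets into the 7 exclusive
regions, each feature annotated with its per-comparison direction.

**Matched analysis** is an additive patient-block design (class
indicators plus patient indicators); whether the original matched
comparison modeled pairing is unstated, and the blocked design is the
standard linear-model rendering of it.

# Survival signatures

`cox_fit()` estimates the log hazard per log2 expression unit, so
`exp(beta)` is the hazard ratio per 2-fold expression change; ties use
the Efron correction by default (Breslow available). Constant covariates
return a flagged non-informative result. `permutation_pvalue()` jointly
permutes the (time, event) pairs `B` times (default 10,000 in the
reference analysis; scaled down in tests), refits, and reports
`(1 + #{|z_perm| >= |z_obs|}) / (B + 1)`, so the smallest attainable
value is `1/(B+1)`. The permutation statistic is the Wald z.

`build_signature()` keeps candidates that pass both the univariate
permutation filter and the multivariate Wald filter (miRNA + age +
ordinal grade, the clinical covariates of the reference analysis) at the
same `alpha`; member coefficients are the multivariate betas, and the
protective (HR < 1) / risk-associated (HR > 1) labels follow the
univariate hazard ratio. Whether univariate significance originally meant
the permutation or the Wald P is unstated; the permutation P is used
because it is the quantity the permutation machinery exists to provide.

**Risk score.** The published analysis never writes the score down. The
implementation uses the standard signature construction: the per-sample
linear predictor `sum(beta_i * x_i)` over the signature miRNAs, split at
the cohort median (ties at the median go to the low-risk group, so group
sizes differ by at most 1 without ties). An alternative reading —
clustering the signature-miRNA submatrix into two groups — is possible
with the clustering module, but the median split is the default and the
two modes are interpretations, not reproductions.

`km_estimate()` (product-limit, median = smallest time with
`S(t) <= 0.5`), `logrank_test()` and `group_hazard_ratio()` (univariate
Cox on the high-vs-low indicator plus per-group KM medians) complete the
Figure-2-style machinery. The log-rank statistic equals the Cox score
test for a binary covariate, which the tests verify numerically.

**Averaging hazard ratios across replicates.** Hazard ratios are
ratio-scale quantities; wherever the tests or the acceptance analysis
average HR estimates over simulation replicates, the geometric mean is
used (the arithmetic mean of `exp(beta_hat)` carries a Jensen inflation
of roughly `exp(var(beta_hat)/2)` — about 5% at 52 events — that says
nothing about estimator quality).

# Integration

`anticorrelated_pairs()` computes Pearson correlations across the matched
(intersection) samples for every predicted miRNA∶gene pair, keeps `r < 0`,
and per miRNA retains the `top_k` most anti-correlated genes. `top_k`
defaults to 20, the largest per-miRNA count in the published correlation
table; correlations are computed on tumor samples in the pipeline
because the published table pairs tumor fold changes. Constant vectors
yield a missing correlation (never 0). `trend_opposition()` counts
strictly opposite logFC signs over the three comparisons (zero logFC has
sign 0 and never opposes) and flags 3/3 as "anti-trend", 2/3 as "mostly
anti".

# Clustering

`spearman_distance()` uses `d = 1 − rho` on mid-ranks (ties averaged),
giving distances in [0, 2]; constant items are excluded and reported.
`average_linkage()` is UPGMA. `cut_tree_at_correlation()` converts a
correlation threshold `r` in [−1, 1] to a cut height `h = 1 − r`:
sub-trees whose merges sit at or below `h` become clusters, so `r = −1`
gives one cluster and `r = 1` gives singletons. The published four gene
subgroups come from an unstated threshold, so the threshold is a config
value, and `threshold_for_clusters()` finds the threshold attaining a
requested cluster count from the merge heights (tied merge heights can
make a count unattainable, which is an explicit error). Raising the
threshold only refines the partition — a property the tests check.

# Workflow

`run_pipeline()` executes simulate → preprocess → diffexpr → survival →
integration → clustering from one config (YAML or list), writes every
table stamped with a config content hash and the seed, and logs stage
timings. A single seed fans out to fixed per-stage child seeds so stages
are independently reproducible; reruns are byte-identical apart from the
timing log. `write_report()` renders the run summary (DE counts, Venn
region sizes, signature members, group HR with KM medians, top
anti-correlated pairs, cluster sizes). The exported functions are the
interface; no shell entry point is shipped because the package is meant
to be driven from R, like the modeling packages it resembles.

# Numerical choices and problem sizes

- Detection SD uses the n−1 denominator; IQR uses the default type-7
  quantiles.
- Cox fits cap Newton–Raphson at 50 iterations and flag non-convergence;
  the permutation loop uses the same fitter with a 25-iteration cap and
  treats a failed refit as infinitely extreme (conservative).
- `trigamma` inversion iterates Newton steps to a relative tolerance of
  1e-10.
- Degenerate inputs are explicit: empty filter results, empty signatures,
  all-censored cohorts and constant covariates return flagged objects or
  errors, never silent zeros.
- Test problem sizes are chosen so the full suite runs in well under a
  minute of simulation-heavy work: recovery tests use 60 samples per
  class (fold changes), n = 1000 tumors (univariate HR), 75 subjects and
  200 replicates per endpoint (group HR), 400/1000 null replicates for
  permutation and log-rank calibration with B = 200. The same analyses
  at the published scale (B = 10,000, 133 candidates) run through the
  identical code path.

# Known limitations

- The exponential baseline hazard makes proportional hazards exact;
  no model misspecification is exercised.
- No proportional-hazards diagnostics, time-varying covariates or
  competing risks.
- Quantile normalization's fold-change compression at the distribution
  extremes (discussed above).
- External cohorts enter only as plain TSV count matrices plus a sample
  annotation table; there is no repository download path, and the
  synthetic generator is the supported and tested input source.
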