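# trisign

Integrated miRNA/mRNA analysis for three-tissue-class profiling studies
of triple-negative breast cancer (TNBC): adjacent normal breast, primary
tumor and regional lymph-node metastasis, profiled with nCounter-style
count panels, with patient survival follow-up.

The package is aimed at analysts who want the full published analysis
recipe as tested, reusable R functions — and at methodologists who want
to study how well each stage recovers known effects, since every stage
can be driven by a seeded synthetic-cohort generator with planted ground
truth.

## What it computes

- **Preprocessing** — per-sample detection thresholds from negative
  controls (mean + 2·SD on log2 counts), removal of undetected
  (below threshold in ≥ half the samples) and invariant (IQR < 0.5)
  features, then quantile or invariant-set normalization.
- **Differential expression** — per-feature linear models on a
  group-means design with the contrasts `N_vs_T = tumor − normal`,
  `N_vs_M = mets − normal`, `T_vs_M = mets − tumor`; empirical-Bayes
  moderated t-statistics with posterior variance
  `(d0·s0² + d_g·s²_g)/(d0 + d_g)`; Benjamini–Hochberg adjustment; Venn
  partitioning of the three DE sets into 7 exclusive regions with
  per-comparison directions.
- **Survival signatures** — univariate Cox fits where `exp(β)` is the
  hazard ratio per 2-fold expression change; permutation P values from
  joint permutation of (time, event) pairs,
  `P = (1 + #{|z_perm| ≥ |z_obs|})/(B + 1)`; signature membership =
  permutation-significant univariate AND Wald-significant multivariate
  (age + grade adjusted); risk score `Σ β_i·x_i` with median split into
  high/low groups; Kaplan–Meier curves, medians, log-rank tests and the
  high-vs-low group hazard ratio.
- **Integration** — Pearson correlation of predicted miRNA∶gene pairs
  across matched tumor samples, keeping the top-k anti-correlated genes
  per miRNA; three-tissue trend-opposition flags (e.g. a miRNA falling
  across normal → tumor → mets while its target rises).
- **Clustering** — Spearman-rank correlation distance (`1 − ρ`),
  average-linkage (UPGMA) trees, and "cutting the tree" at a correlation
  threshold `r` (height `1 − r`) into flat clusters.
- **Synthetic cohorts** — count matrices for the three classes with
  planted log2 fold changes, matched pairs, negative controls,
  proportional-hazards survival with per-miRNA hazard ratios, tuned
  uniform censoring, planted anti-correlated miRNA∶gene pairs and decoy
  target predictions, all bit-reproducible from a seed.

## Worked example

One config drives the whole chain. Here a synthetic cohort gets a known
tumor fold change of 2.29 on `miR-sim-001`, two prognostic miRNAs with
per-doubling hazard ratios 2.0 and 0.5, and one anti-correlated
miRNA∶gene pair among 50 decoy predictions:

```r
library(trisign)

config <- list(
  simulate = list(
    n_normal = 40, n_tumor = 75, n_mets = 30, n_matched_pairs = 20,
    n_mirna = 60, n_mrna = 40,
    planted_de = data.frame(probe = c("miR-sim-001", "miR-sim-002"),
                            comparison = c("N_vs_T", "N_vs_M"),
                            logFC = c(2.29, -1.8)),
    survival = list(betas = c("miR-sim-003" = log(2),
                              "miR-sim-004" = log(0.5)),
                    baseline_hazard = 0.01, censoring_fraction = 0.2),
    planted_pairs = data.frame(mirna = "miR-sim-001", gene = "GENE001",
                               slope = -1, noise_sd = 0.2),
    n_decoy_pairs = 50),
  permutations = 500, cluster_k = 4, seed = 20)

res <- run_pipeline(config, "demo_run")
cat(write_report(res), sep = "\n")
```

which prints (abridged):

```
trisign run report (config 1b3f41d1, seed 20)

Differentially expressed miRNAs:
  N_vs_T: 7
  N_vs_M: 7
  T_vs_M: 3
Venn region sizes:
  N_vs_T: 4
  N_vs_M: 2
  ...

Survival signature (OS), 6 members:
  miR-sim-003: HR 1.91 (1.16-3.16), perm P 0.0240, risk-associated
  miR-sim-004: HR 0.55 (0.30-1.01), perm P 0.0459, protective
  ...
  High vs low risk: HR 3.79 (95% CI 2.08-6.91), P 0.0000
  Median survival high/low: 65.4 / 278.2 months
  Log-rank P: 0.0000

Top anti-correlated miRNA:mRNA pairs:
  miR-sim-001 ~ GENE001: r -0.59
  ...

Clusters at r >= -0.03: 4 clusters of sizes 5, 16, 10, 8
```

Reading it: both planted prognostic miRNAs are in the signature with
hazard ratios near their planted values (2.0 and 0.5) and the correct
protective/risk labels; the remaining members are the false positives
expected when screening 60 candidates at `alpha = 0.05`. The risk-score
split separates survival sharply (the cohort was built that way), and
the planted miRNA∶gene pair tops the anti-correlation table with `r`
close to its design value `slope·sd(x)/sd(y) ≈ −0.6` at these noise
settings. Stage tables (`de_mirna.tsv`, `venn.tsv`, `signature.json`,
`risk_groups.tsv`, `km_curves.tsv`, `correlation_pairs.tsv`,
`clusters.tsv`) land in `demo_run/`, each stamped with the config hash
and seed; rerunning the same config reproduces them byte for byte.

Individual stages are ordinary functions — `preprocess_counts()`,
`run_diffexpr()`, `cox_fit()`, `permutation_pvalue()`,
`build_signature()`, `risk_score()`, `km_estimate()`, `logrank_test()`,
`anticorrelated_pairs()`, `trend_opposition()`, `spearman_distance()`,
`average_linkage()`, `cut_tree_at_correlation()` — see the methods
vignette (`vignettes/trisign-methods.Rmd`) for the models and the design
decisions behind them.

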