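---
title: "Methods: co-expression eigengenes and Cox partial-likelihood networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression eigengenes and Cox partial-likelihood networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`eigensurv` predicts censored survival outcomes from multi-omics data in
two stages.

**Stage 1 — dimension reduction by co-expression modules.** Gene-level
expression (features $\times$ samples) is first filtered: the lowest 20%
of features by row mean are removed, then the lowest 20% of the
survivors by unbiased row variance. On the filtered matrix a
feature–feature Spearman correlation network is built, edge weights are
the absolute correlations normalised spectral-clustering style,
$w'_{ij} = w_{ij} / \sqrt{d_i d_j}$ with $d_i = \sum_k w_{ik}$, and
densely connected modules are mined greedily (lmQCM): high-weight edges
seed clusters, clusters absorb the best-connected outside vertex while
the density $2\sum_{i<j\in C} w'_{ij} / (|C|(|C|-1))$ stays above a
decaying bound $\alpha_n = 1 - 1/(2\lambda(n+t))$, overlapping clusters
merge when $|A \cap B| / \min(|A|,|B|) \ge \beta$, and clusters below
`min_size` are dropped. Each module is summarised into its *eigengene*:
member genes are z-scored across samples and the first right-singular
vector of the standardised submatrix becomes one "super-gene" per
module. A transcriptome of $10^4$ features typically collapses to a few
dozen eigengenes.

**Stage 2 — a multi-branch Cox network.** Each omics block feeds its own
branch: eigengene blocks pass through one small sigmoid hidden layer
(defaults: 8 units for mRNA, 4 for miRNA); scalar covariates (copy
number burden, tumour mutation burden, age, ER, PR) connect to the
output directly. The concatenated branch outputs $z$ enter a single
linear Cox unit $\eta = \beta^\top z$. Training minimises the negative
log partial likelihood

$$-\ell = -\sum_{i:\,C_i = 1}\Big(\eta_i -
  \log \sum_{j:\,Y_j \ge Y_i} e^{\eta_j}\Big) + \lambda \lVert\Theta\rVert_1$$

over all network parameters $\Theta$ by minibatch Adam. Keeping the
branches separate means each data type contributes to the hazard
independently, which is what makes single-feature ablation
interpretable at the module level.

**Evaluation.** Harrell's concordance index on held-out folds;
Kaplan–Meier curves and the two-group log-rank test after splitting the
concatenated test risks at their median. Feature importance is
zero-ablation: with a trained model fixed, one input feature at a time
is forced to zero on the test data and the drop in test concordance is
recorded; features are ranked by the median drop across folds.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.7 (mRNA), 0.4 (miRNA) | seed threshold on \|correlation\| for new clusters |
| `lam`, `t` | 1, 1 | density-decay schedule of cluster expansion |
| `beta` (merge) | 0.4 (mRNA), 0.6 (miRNA) | overlap ratio above which clusters merge |
| `min_size` | 10 (mRNA), 4 (miRNA) | smallest retained module |
| hidden dims | 8 (mRNA), 4 (miRNA) | branch widths; covariates have none |
| `epochs` | 100 | Adam passes over the training fold |
| `batch_size` | 64 | minibatch size; risk sets are computed within batches |
| `learning_rate` | 0.01 | Adam step size (stable on ~74-dim inputs) |
| `l1_lambda` | 1e-5 | LASSO multiplier on all parameters |

## Design choices where the design was open

* **Where the sigmoid sits.** Hidden branches use sigmoid activations
  and the displayed per-patient "hazard ratio" is `sigmoid(eta)`, but
  the partial likelihood is evaluated on the *linear* predictor
  $\eta$. The sigmoid is strictly monotone, so every ranking metric
  (c-index, median split) is identical either way, while the linear
  scale keeps the likelihood well conditioned.
  `train_config(likelihood_on = "sigmoid")` preserves the literal
  alternative.
* **Seed-test scale in module mining.** Cluster seeding tests edges on
  the raw absolute correlation (`seed_on = "raw"`), not on the
  degree-normalised weights, although expansion runs on the normalised
  weights. After normalisation, $w'_{ij}$ of a chance edge between two
  low-degree background features routinely exceeds every within-module
  weight in small cohorts, so a relative threshold on normalised
  weights seeds noise instead of signal; the conventional
  gamma values (0.7, 0.4) also read naturally as correlation-scale
  thresholds. `seed_on = "normalized"` restores the other reading.
* **Ties.** Breslow's approximation: tied event times share the full
  risk set. It is the simplest extension consistent with the risk-set
  sum $\sum_{Y_j \ge Y_i}$.
* **Minibatch risk sets.** Risk sets are computed within each batch of
  64; `full_batch = TRUE` gives exact risk sets (used in the
  recovery tests, where the fit must match a Newton–Raphson Cox
  oracle).
* **Eigengene sign.** SVD signs are arbitrary, so each eigengene is
  flipped to correlate non-negatively with its module's mean
  standardised profile — deterministic across LAPACK builds.
* **Quantile filtering as a count.** "Lowest 20%" removes exactly
  `floor(0.2 n)` features, with ties broken by original row order:
  deterministic under ties, unlike a percentile-value cut.
* **Median split.** Samples exactly at the median risk go to the
  low-risk group; group sizes then differ by at most the number of
  exact ties.
* **Input scaling.** All Cox-layer inputs are z-scored on the training
  fold and the same transform is applied to the test fold, so the
  scalar covariates (age in years, burden counts) enter on the same
  scale as eigengenes. Ablation zeroes the *standardised* input — zero
  is the natural centre there; `ablate_scale = "raw"` zeroes the raw
  value instead.
* **Module mining on the full cohort.** `build_bundle` mines modules
  once on all samples, as the published module counts imply. This
  leaks unsupervised correlation structure (never outcomes) across CV
  folds; pass fold-restricted matrices to `build_bundle` per fold for a
  strictly leakage-free variant.
* **Bias terms.** Layers carry biases by default (they help the tiny
  hidden layers), but `count_trainable_weights(include_bias = FALSE)`
  reproduces the published parameter arithmetic, and
  `use_bias = FALSE` trains exactly the counted model. The L1 penalty
  covers every parameter uniformly, biases included.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws one standard-normal latent factor per planted
module, makes member genes noisy copies of it
(`loading * factor + N(0, noise_sd)`, so within-module correlation is
$1/(1+\sigma^2)$ for unit loading), and leaves background genes as pure
noise. Covariates are independent: age uniform on 26–90, ER/PR
Bernoulli at 76.16% / 67.41% positivity, burdens log-normal — the shape
of a 583-patient breast-cancer cohort. Event times follow
$T = -\log(U) / (h_0 e^{\eta})$ with an exponential baseline whose
median survival at $\eta = 0$ is 31.7 months, and censoring is uniform
with its horizon solved numerically to hit the target censored fraction
(default 30%, a typical working value when the cohort's own event rate
is not modelled).

Defaults are desk-scale on the gene axis (hundreds of genes, not 13k):
full-transcriptome correlation matrices would need gigabytes without
changing what the tests establish. The generator does **not** emulate
RSEM count noise, library-size effects, batch structure, correlated
covariates, or informative censoring. A green test therefore
establishes algorithmic correctness (module recovery, likelihood
optimisation, calibration, ranking) — not clinical performance on real
cohorts, whose headline concordance values are data-dependent and out
of scope here.

## Numerical choices

* The partial likelihood uses a log-sum-exp shift, so predictors up to
  ~700 in magnitude are safe; `sigmoid` is evaluated branch-wise and
  never overflows.
* Gradients are analytic (backpropagation through the branches and an
  $O(n \log n)$ cumulative-sum form of the Cox gradient) and are
  checked against central finite differences to $10^{-5}$ in the test
  suite.
* Training aborts with a diagnostic on a non-finite loss (learning rate
  too high) rather than returning NaN parameters.
* Weight initialisation is seeded uniform on
  $[-1/\sqrt{\text{fan-in}}, +1/\sqrt{\text{fan-in}}]$; two runs with
  one seed are bit-identical on one thread.
* An event-free minibatch contributes only the L1 penalty; an
  event-free evaluation batch returns 0 with a warning.
* Zero-variance features: correlations set to 0 with a warning (ranks
  are undefined); in z-scoring their rows stay centred at zero.

## Known limitations

* The greedy lmQCM expansion is quadratic in features per cluster step;
  fine to a few thousand features, not for whole-genome single-cell
  scales.
* Per-fold "fine-tuned" learning rates are not searched automatically;
  the default 0.01 is exposed, not optimised.
* Concatenating risks across folds for one log-rank test (the published
  procedure, reproduced here) mixes scores from differently scaled
  fold models; the median split is applied to the pooled vector as
  published, and this caveat is inherited.
* No time-dependent AUC, Uno's C, or competing-risks support.
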