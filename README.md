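# eigensurv

Survival prognosis from multi-omics data via co-expression module
eigengenes and a multi-branch Cox partial-likelihood network.

## Who this is for

Cancer-genomics and biostatistics analysts who have, per patient, bulk
expression matrices (mRNA, miRNA), a few scalar genomic/clinical
covariates (copy number burden, tumour mutation burden, diagnosis age,
ER/PR status), and right-censored overall-survival outcomes — and who
want a prognostic model that is small enough to train on a few hundred
patients and interpretable at the level of co-expression modules rather
than individual genes.

## The method in brief

1. **Filter** expression features: drop the lowest 20% by mean, then
   the lowest 20% of survivors by variance.
2. **Mine modules** on the Spearman correlation network with lmQCM
   (local maximal Quasi-Clique Merger): seed at high-correlation edges,
   grow while the cluster density stays above a decaying bound
   `alpha_n = 1 - 1/(2*lambda*(n+t))`, merge clusters overlapping by at
   least `beta`, keep clusters of at least `min_size`. Overlap between
   modules is allowed.
3. **Summarise** each module into its *eigengene* — the first
   right-singular vector of the z-scored module submatrix — giving a
   modules-by-samples matrix.
4. **Train** the branched Cox network: eigengene blocks pass through
   small sigmoid hidden layers (8 units mRNA, 4 miRNA), covariates pass
   straight through, and a single Cox unit produces the linear
   predictor `eta` whose negative log partial likelihood (Breslow ties)

   `-l(Theta) = -sum_{i: C_i=1} [ eta_i - log sum_{j: Y_j >= Y_i} exp(eta_j) ] + lambda*||Theta||_1`

   is minimised by minibatch Adam. `sigmoid(eta)` is reported as the
   per-patient hazard ratio in (0, 1).
5. **Evaluate** with Harrell's concordance index per held-out fold,
   plus a median-split log-rank test on the concatenated test risks;
   **rank features** by the median drop in test concordance when each
   input is zeroed under the trained model (zero-ablation importance).

With eigengene inputs the full design has 57*8 + 12*4 + 17 = 521
trainable weights instead of the 13132*8 + 530*4 + 17 = 107193 needed
for raw features — a 99.46% reduction of the input space that makes the
network learnable on a ~580-patient cohort.

## Worked example

A fully synthetic 400-patient cohort with four planted mRNA modules and
two miRNA modules, where only the first mRNA module's latent factor
carries survival signal (log-hazard coefficient 1.5, ~30% censoring):

```r
library(eigensurv)

co <- generate_cohort(synthetic_spec(
  n_samples = 400, n_genes = 200,
  module_plan = data.frame(size = c(25, 25, 20, 20), loading = 1,
                           noise_sd = 0.5),
  n_mirna = 40,
  mirna_module_plan = data.frame(size = c(8, 6), loading = 1,
                                 noise_sd = 0.5),
  factor_coefs = c(1.5, 0, 0, 0, 0, 0),
  covariate_coefs = c(Age = 0, ER = 0, PR = 0),
  censoring = 0.3, seed = 9))

built <- build_bundle(co$mrna, co$covariates, co$survival,
                      mirna = co$mirna)
res <- run_combination(built$bundle, "vi", train_config(seed = 4), k = 5)
res
#> <combo_result 'vi'> 10 features
#>   c-index: median 0.7751, mean 0.7667 (folds: 0.746, 0.728, 0.775, 0.801, 0.783)
#>   log-rank: chisq 71.466, p 2.82e-17

tab <- rank_features(res$models, res$test_bundles)
head(as.data.frame(tab)[, c("feature", "block", "median_delta")], 3)
#>   feature    block median_delta
#> 1  mRNA_3     mrna -0.219008264
#> 2 miRNA_1    mirna -0.003588517
#> 3      PR clinical -0.002186589
```

Reading the output: the mined eigengene `mRNA_3` is the module that
recovered the planted hazardous factor (|correlation| 0.99 with the
truth); zeroing it on the test folds costs a median 0.22 of concordance,
ranking it first, while the noise modules and null covariates sit near
zero. The median test c-index of 0.78 against the 0.5 chance level, and
the log-rank p of 3e-17 for the median-risk split, say the fitted risks
separate the synthetic cohort sharply.

The deterministic 12-sample `worked_example_cohort()` used throughout
the unit tests exercises the same pipeline in miniature, and
`write_cohort()` / `read_expression()` / `read_clinical()` round-trip
cohorts through plain TSV files. A thin CLI wrapping the same calls
lives at `inst/cli/eigensurv.R`
(`Rscript inst/cli/eigensurv.R run --combo vi --seed 7 data/ report/`).

## Scope notes

The package ships no cohort data and no download clients; real-cohort
headline numbers (median c-index, cohort log-rank p-values) are
data-dependent and not reproduced here. See
`vignettes/eigensurv-methods.Rmd` for the modelling assumptions, the
open design decisions and their rationale, and what the synthetic
cohorts do and do not emulate.
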