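# End-to-end experiment harness: k-fold cross-validation, the six
# omics-combination designs, concatenated-fold survival analysis, and
# report assembly.

#' Build k cross-validation folds
#'
#' Disjoint, exhaustive test-index sets whose sizes differ by at most
#' one, drawn by a seeded shuffle.  The optional event-stratified
#' variant shuffles within event strata so every fold receives its share
#' of events (useful when folds are small).
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratify optional 0/1 vector (e.g. event indicators) to
#'   stratify on.
#' @return list of `k` integer index vectors (the test sets).
#' @export
make_folds <- function(n, k = 5, seed = 1, stratify = NULL) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  if (is.null(stratify)) {
    perm <- sample.int(n)
  } else {
    stopifnot(length(stratify) == n)
    perm <- unlist(lapply(split(seq_len(n), stratify), sample),
                   use.names = FALSE)
  }
  fold_of <- rep(seq_len(k), length.out = n)
  unname(split(perm, fold_of))
}

#' Omics blocks required by a named combination
#'
#' The six published input designs plus a transcriptomics-free
#' reference: `i` mRNA modules only; `ii` miRNA modules only; `iii`
#' mRNA + miRNA; `iv` adds copy-number and mutation burden; `v` mRNA +
#' miRNA + clinical (age, ER, PR); `vi` everything;
#' `covariates_only` the 5 scalar covariates without transcriptomics.
#'
#' @param combo one of `"i", "ii", "iii", "iv", "v", "vi",
#'   "covariates_only"`.
#' @return character vector of block names.
#' @export
combo_blocks <- function(combo = c("i", "ii", "iii", "iv", "v", "vi",
                                   "covariates_only")) {
  combo <- match.arg(combo)
  switch(combo,
         i = "mrna",
         ii = "mirna",
         iii = c("mrna", "mirna"),
         iv = c("mrna", "mirna", "cnb_tmb"),
         v = c("mrna", "mirna", "clinical"),
         vi = c("mrna", "mirna", "cnb_tmb", "clinical"),
         covariates_only = c("cnb_tmb", "clinical"))
}

#' Cox-layer input dimension of a combination on a bundle
#'
#' @param bundle an [omics_bundle].
#' @param combo combination name, see [combo_blocks].
#' @return integer feature count.
#' @export
combo_input_dim <- function(bundle, combo) {
  blocks <- combo_blocks(combo)
  missing <- setdiff(blocks, names(bundle$blocks))
  if (length(missing))
    stop(sprintf("combo '%s' needs missing block(s): %s", combo,
                 paste(missing, collapse = ", ")))
  sum(vapply(bundle$blocks[blocks], nrow, integer(1)))
}

# train/test over folds; fold k trains with seed = config$seed + k
cv_train_test <- function(bundle, folds, config = train_config(),
                          hidden_dims = c(mrna = 8, mirna = 4)) {
  models <- vector("list", length(folds))
  test_bundles <- vector("list", length(folds))
  cindex <- numeric(length(folds))
  risks <- list()
  n <- length(bundle$sample_ids)
  for (k in seq_along(folds)) {
    test_idx <- folds[[k]]
    train_idx <- setdiff(seq_len(n), test_idx)
    btr <- subset_bundle(bundle, samples = train_idx)
    bte <- subset_bundle(bundle, samples = test_idx)
    cfg <- config
    cfg$seed <- config$seed + k
    arch <- architecture_from_bundle(btr, hidden_dims,
                                     use_bias = cfg$use_bias)
    models[[k]] <- train_coxnet(btr, arch, cfg)
    test_bundles[[k]] <- bte
    r <- forward(models[[k]], bte)
    risks[[k]] <- r
    cindex[k] <- concordance_index(r, bte$survival)
  }
  list(models = models, test_bundles = test_bundles, cindex = cindex,
       risks = risks, folds = folds)
}

#' Run one omics combination through cross-validated training
#'
#' Selects the combination's blocks (pruning unused network branches),
#' trains and tests per fold, concatenates the test risks of all folds,
#' and runs the median-split log-rank test on the concatenated risks.
#'
#' @param bundle an [omics_bundle] holding at least the blocks the
#'   combination needs.
#' @param combo combination name, see [combo_blocks].
#' @param config a [train_config]; `config$seed` also seeds the folds.
#' @param k number of folds (default 5).
#' @param hidden_dims named hidden widths for eigengene branches.
#' @param stratify_folds stratify folds by event status (default FALSE).
#' @return list of class `combo_result`: `combo`, `n_features`,
#'   `per_fold_cindex`, `median_cindex`, `mean_cindex`, `risks`
#'   (concatenated, named by sample), `labels` (median split),
#'   `logrank` (chisq, p_value), `models`, `test_bundles`, `folds`.
#' @export
run_combination <- function(bundle, combo, config = train_config(),
                            k = 5, hidden_dims = c(mrna = 8, mirna = 4),
                            stratify_folds = FALSE) {
  n_feat <- combo_input_dim(bundle, combo)   # errors on missing blocks
  sub <- bundle
  sub$blocks <- bundle$blocks[combo_blocks(combo)]
  sub <- omics_bundle(sub$blocks, bundle$survival)
  folds <- make_folds(length(sub$sample_ids), k = k, seed = config$seed,
                      stratify = if (stratify_folds) sub$survival$event)
  cv <- cv_train_test(sub, folds, config, hidden_dims)
  risk_all <- unlist(cv$risks)
  surv_all <- do.call(rbind, lapply(folds, function(f)
    sub$survival[f, c("time", "event")]))
  ms <- median_split_logrank(risk_all,
                             survival_data(surv_all$time, surv_all$event,
                                           names(risk_all)))
  structure(list(combo = combo, n_features = n_feat,
                 per_fold_cindex = cv$cindex,
                 median_cindex = stats::median(cv$cindex),
                 mean_cindex = mean(cv$cindex),
                 risks = risk_all, labels = ms$labels,
                 logrank = ms$logrank,
                 models = cv$models, test_bundles = cv$test_bundles,
                 folds = folds),
            class = "combo_result")
}

#' @export
print.combo_result <- function(x, ...) {
  cat(sprintf("<combo_result '%s'> %d features\n", x$combo, x$n_features))
  cat(sprintf("  c-index: median %.4f, mean %.4f (folds: %s)\n",
              x$median_cindex, x$mean_cindex,
              paste(sprintf("%.3f", x$per_fold_cindex), collapse = ", ")))
  cat(sprintf("  log-rank: chisq %.3f, p %.3g\n",
              x$logrank$chisq, x$logrank$p_value))
  invisible(x)
}

#' Pairwise paired t-tests between combination results
#'
#' For every ordered pair of runs, the per-fold concordance indices are
#' compared by a paired t-test (`t(a, b) = -t(b, a)`).
#'
#' @param results named list of `combo_result` objects or plain per-fold
#'   c-index vectors.
#' @return list with matrices `t` and `p_value` (rows = set 1,
#'   columns = set 2).
#' @export
compare_combinations <- function(results) {
  cvs <- lapply(results, function(r)
    if (inherits(r, "combo_result")) r$per_fold_cindex else as.numeric(r))
  nm <- names(cvs)
  if (is.null(nm)) nm <- paste0("run", seq_along(cvs))
  k <- length(cvs)
  tmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pmat <- tmat
  for (a in seq_len(k)) for (b in seq_len(k)) {
    tt <- paired_t_test(cvs[[a]], cvs[[b]])
    tmat[a, b] <- tt$t
    pmat[a, b] <- tt$p_value
  }
  list(t = tmat, p_value = pmat)
}

#' Assemble a full omics bundle from expression data and covariates
#'
#' The standard pre-network pipeline: filter each expression block by
#' mean then variance, mine co-expression modules on the (full) cohort,
#' summarise them into eigengene matrices, and bundle them with the
#' scalar covariates split into `cnb_tmb` and `clinical` blocks.
#' Mining on the full cohort mirrors the published design; pass
#' per-fold-restricted matrices for a strictly leakage-free variant.
#'
#' @param mrna an [expression_matrix] (genes x samples).
#' @param covariates 5 x samples matrix with rows
#'   `CNB`, `TMB`, `Age`, `ER`, `PR` (or `NULL` to omit).
#' @param survival a [survival_data].
#' @param mirna optional miRNA [expression_matrix].
#' @param mrna_params [lmqcm_params] for the mRNA block.
#' @param mirna_params [lmqcm_params] for the miRNA block.
#' @param mean_frac,var_frac filtering fractions (defaults 0.2).
#' @return list with `bundle` ([omics_bundle]), `mrna_modules`,
#'   `mirna_modules` (module sets).
#' @export
build_bundle <- function(mrna, covariates, survival, mirna = NULL,
                         mrna_params = lmqcm_params(gamma = 0.7, beta = 0.4,
                                                    min_size = 10),
                         mirna_params = lmqcm_params(gamma = 0.4, beta = 0.6,
                                                     min_size = 4),
                         mean_frac = 0.2, var_frac = 0.2) {
  prep <- function(x) filter_by_variance(filter_by_mean(x, mean_frac),
                                         var_frac)
  mine <- function(x, p, src) {
    cm <- correlation_matrix(x, p$correlation)
    lmqcm_mine(lmqcm_weights(cm), p, source = src)
  }
  mr <- prep(mrna)
  mr_mod <- mine(mr, mrna_params, "mrna")
  blocks <- list(mrna = unclass(eigengene_matrix(mr, mr_mod,
                                                 prefix = "mRNA_")))
  mi_mod <- NULL
  if (!is.null(mirna)) {
    mi <- prep(mirna)
    mi_mod <- mine(mi, mirna_params, "mirna")
    em <- eigengene_matrix(mi, mi_mod, prefix = "miRNA_")
    if (nrow(em)) blocks$mirna <- unclass(em)
  }
  if (!is.null(covariates)) {
    blocks$cnb_tmb <- covariates[c("CNB", "TMB"), , drop = FALSE]
    blocks$clinical <- covariates[c("Age", "ER", "PR"), , drop = FALSE]
  }
  list(bundle = omics_bundle(blocks, survival),
       mrna_modules = mr_mod, mirna_modules = mi_mod)
}

#' Fraction of input features removed by module summarisation
#'
#' `1 - n_summary / n_raw`, reported as a percentage rounded to
#' `digits` decimals (e.g. 13,132 + 530 raw transcriptomic features
#' reduced to 57 + 12 modules + 5 covariates gives 99.46).
#'
#' @param n_raw raw input feature count.
#' @param n_summary summarised feature count.
#' @param digits decimals in the percentage (default 2).
#' @return percentage reduced.
#' @export
feature_reduction_pct <- function(n_raw, n_summary, digits = 2) {
  round(100 * (1 - n_summary / n_raw), digits)
}
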