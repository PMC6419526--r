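# Zero-ablation feature importance: force one Cox-input feature to zero
# in the test data under a fixed trained model, measure the change in
# test concordance index, and rank features by the median change across
# cross-validation folds (most negative = most important).

#' Zero out one feature of a bundle
#'
#' Returns a copy of the bundle with the named feature's values set to
#' zero for every sample.  Note that model-based ranking
#' ([rank_features]) zeroes at the network input (after the training
#' standardisation) via `forward(..., ablate =)`; this raw-scale helper
#' exists for pipelines that pre-standardise their bundles.
#'
#' @param bundle an [omics_bundle].
#' @param feature a feature id present in the bundle.
#' @return the modified [omics_bundle].
#' @export
ablate_feature <- function(bundle, feature) {
  stopifnot(length(feature) == 1)
  found <- FALSE
  for (nm in names(bundle$blocks)) {
    hit <- rownames(bundle$blocks[[nm]]) == feature
    if (any(hit)) {
      bundle$blocks[[nm]][hit, ] <- 0
      found <- TRUE
    }
  }
  if (!found) stop(sprintf("unknown feature '%s'", feature))
  bundle
}

#' Rank features by zero-ablation concordance loss
#'
#' For every fold and every Cox-input feature, the feature's network
#' input is forced to zero on the test bundle and the change in test
#' concordance index `delta = C(ablated) - C(baseline)` is recorded.
#' Features are sorted by median delta ascending (ties broken by mean
#' delta, then feature name), so the most damaging ablations rank
#' first.
#'
#' @param models list of `coxnet_model`, one per fold.
#' @param bundles_test list of test [omics_bundle], one per fold.
#' @param ablate_scale passed to [forward]; default `"standardized"`.
#' @return data frame of class `importance_table`: `feature`, `block`,
#'   one `delta_fold<k>` column per fold, `median_delta`, `mean_delta`,
#'   `rank`.
#' @export
rank_features <- function(models, bundles_test,
                          ablate_scale = c("standardized", "raw")) {
  ablate_scale <- match.arg(ablate_scale)
  stopifnot(length(models) >= 1, length(models) == length(bundles_test))
  feats <- bundle_feature_ids(bundles_test[[1]])
  n_fold <- length(models)
  deltas <- matrix(NA_real_, length(feats), n_fold,
                   dimnames = list(feats, paste0("delta_fold", seq_len(n_fold))))
  for (k in seq_len(n_fold)) {
    bt <- bundles_test[[k]]
    surv <- bt$survival
    base <- concordance_index(forward(models[[k]], bt), surv)
    for (f in seq_along(feats)) {
      risk <- forward(models[[k]], bt, ablate = feats[f],
                      ablate_scale = ablate_scale)
      deltas[f, k] <- concordance_index(risk, surv) - base
    }
  }
  med <- apply(deltas, 1, stats::median)
  mn <- rowMeans(deltas)
  ord <- order(med, mn, feats)
  out <- data.frame(feature = feats[ord], block = names(feats)[ord],
                    deltas[ord, , drop = FALSE],
                    median_delta = med[ord], mean_delta = mn[ord],
                    rank = seq_along(feats),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("importance_table", "data.frame"))
}

#' Retrain on selected features only
#'
#' Applies a selection rule to an importance table (default: keep
#' features whose median ablation delta is negative, i.e. whose removal
#' hurts test concordance), subsets every fold's bundles to the selected
#' features, retrains per fold, and reports the per-fold test
#' concordance indices.  When baseline per-fold indices are supplied the
#' before/after comparison is summarised by [paired_t_test].
#'
#' @param table an `importance_table` from [rank_features].
#' @param bundle the full [omics_bundle].
#' @param folds fold index sets from [make_folds] (test indices).
#' @param config a [train_config]; fold k trains with
#'   `seed = config$seed + k`.
#' @param hidden_dims named hidden widths for [architecture_from_bundle].
#' @param rule function mapping the table to a logical keep-vector;
#'   default `median_delta < 0`.
#' @param baseline_cindex optional numeric per-fold baseline c-indices.
#' @return list with `selected`, `cindex` (per fold), and `comparison`
#'   (paired t-test vs baseline, or `NULL`).
#' @export
select_and_retrain <- function(table, bundle, folds,
                               config = train_config(),
                               hidden_dims = c(mrna = 8, mirna = 4),
                               rule = function(tab) tab$median_delta < 0,
                               baseline_cindex = NULL) {
  keep <- rule(table)
  selected <- table$feature[keep]
  if (!length(selected)) stop("selection rule retained no features")
  sub <- subset_bundle(bundle, features = selected)
  res <- cv_train_test(sub, folds, config, hidden_dims)
  comparison <- if (!is.null(baseline_cindex))
    paired_t_test(res$cindex, baseline_cindex)
  list(selected = selected, cindex = res$cindex, comparison = comparison)
}

#' Partition a bundle into age strata
#'
#' Splits samples by closed age intervals `[low, high]`; samples falling
#' outside every interval are dropped with a message.  Each stratum can
#' then be run through the full cross-validation and ranking pipeline.
#'
#' @param bundle an [omics_bundle].
#' @param bounds list of `c(low, high)` pairs, e.g.
#'   `list(c(26, 50), c(51, 70), c(71, 90))`.
#' @param age ages: a numeric vector over samples, or the id of a
#'   feature row holding age (default `"Age"`).
#' @return named list of [omics_bundle], one per interval
#'   (`"26-50"` etc.).
#' @export
stratify_by_age <- function(bundle, bounds = list(c(26, 50), c(51, 70),
                                                  c(71, 90)),
                            age = "Age") {
  if (is.character(age)) {
    ids <- bundle_feature_ids(bundle)
    if (!age %in% ids) stop(sprintf("no feature '%s' in bundle", age))
    blk <- names(ids)[ids == age]
    age <- as.numeric(bundle$blocks[[blk]][age, ])
  }
  stopifnot(length(age) == length(bundle$sample_ids))
  out <- list()
  assigned <- logical(length(age))
  for (b in bounds) {
    sel <- which(age >= b[1] & age <= b[2])
    assigned[sel] <- TRUE
    out[[sprintf("%g-%g", b[1], b[2])]] <-
      subset_bundle(bundle, samples = sel)
  }
  if (any(!assigned))
    message(sprintf("stratify_by_age: %d sample(s) outside all bounds dropped",
                    sum(!assigned)))
  out
}

#' Export an importance table as TSV
#' @param table an `importance_table`.
#' @param path output path.
#' @export
write_importance <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
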