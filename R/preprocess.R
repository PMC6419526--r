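# Two-step expression filtering applied before co-expression analysis:
# drop the lowest-mean fraction of features, then the lowest-variance
# fraction of the survivors.

filter_by_stat <- function(expr, fraction, stat) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction))
    stop("`fraction` must be a single number")
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  n <- nrow(expr)
  if (!n) stop("empty expression matrix")
  n_remove <- floor(fraction * n)
  if (n_remove == 0) return(expr)
  s <- stat(expr)
  # stable order by (statistic, original row index): remove exactly
  # n_remove rows, ties resolved by position for determinism
  drop_idx <- order(s, seq_len(n))[seq_len(n_remove)]
  keep <- setdiff(seq_len(n), drop_idx)   # preserves original order
  expression_matrix(unclass(expr)[keep, , drop = FALSE])
}

#' Remove the lowest-mean fraction of features
#'
#' Drops exactly `floor(fraction * n)` features with the smallest row
#' means; surviving rows keep their order and values.  Ties at the cut
#' are broken by original row position.
#'
#' @param expr an [expression_matrix].
#' @param fraction fraction to remove, in `[0, 1)`; default 0.2.
#' @return The filtered [expression_matrix].
#' @export
filter_by_mean <- function(expr, fraction = 0.2) {
  filter_by_stat(expr, fraction, rowMeans)
}

#' Remove the lowest-variance fraction of features
#'
#' As [filter_by_mean] but ranking features by unbiased row variance
#' (divisor n - 1).
#'
#' @inheritParams filter_by_mean
#' @return The filtered [expression_matrix].
#' @export
filter_by_variance <- function(expr, fraction = 0.2) {
  filter_by_stat(expr, fraction, row_vars)
}

row_vars <- function(m) {
  ctr <- m - rowMeans(m)
  rowSums(ctr * ctr) / (ncol(m) - 1)
}
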