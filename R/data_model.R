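# Core typed containers and delimited-text readers/writers shared by all
# pipeline stages.  Matrices are stored features x samples throughout.

#' Construct an expression matrix
#'
#' A thin, validated wrapper around a numeric features x samples matrix.
#' Row names are feature identifiers (genes, miRNAs, eigengene modules),
#' column names are sample identifiers.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @return A numeric matrix of class `expression_matrix` with dimnames set.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2),
#'                        feature_ids = c("g1", "g2", "g3"),
#'                        sample_ids  = c("s1", "s2"))
#' @export
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(sample_ids, "sample")
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(dup, collapse = ", ")))
  invisible(ids)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from a delimited file
#'
#' The file must carry a header row of sample identifiers and a first
#' column of feature identifiers; all remaining cells must be numeric.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("expected a feature-id column plus >=1 sample column")
  feature_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' (value '%s')",
                 feature_ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  }
  if (anyNA(num)) stop("missing values are not allowed in expression input")
  expression_matrix(num, feature_ids = feature_ids,
                    sample_ids = colnames(vals))
}

#' Write an expression matrix to a delimited file
#'
#' Values are written with 15 significant digits so that a
#' read/write round trip preserves them to at least 12 significant digits.
#'
#' @param expr an [expression_matrix] (or any named numeric matrix).
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param id_column name used for the feature-id header cell.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, dialect = c("tsv", "csv"),
                             id_column = "feature_id") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(rownames(expr),
                   signif_chr(unclass(expr)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(expr))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_chr <- function(m) {
  out <- vapply(as.vector(m), function(v) format(v, digits = 15),
                character(1))
  array(out, dim = dim(m))
}

#' Construct survival data
#'
#' Per-sample follow-up time (months) and event indicator.
#'
#' @param time non-negative numeric vector, overall-survival months.
#' @param event 0/1 vector; 1 marks an observed death.
#' @param sample_ids optional character vector of sample identifiers.
#' @return A data frame of class `survival_data` with columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_data <- function(time, event, sample_ids = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event))
    stop("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing survival values")
  if (any(time < 0)) stop("survival times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(time))
  sample_ids <- as.character(sample_ids)
  check_unique_ids(sample_ids, "sample")
  structure(data.frame(sample_id = sample_ids, time = time,
                       event = as.integer(event),
                       stringsAsFactors = FALSE),
            class = c("survival_data", "data.frame"))
}

#' Read a clinical table
#'
#' Expects columns `sample_id`, `os_months`, `os_event`, `age`, `er`,
#' `pr`, `cnb`, `tmb`.  ER/PR values are coerced to 1 = positive,
#' 0 = negative; any other level (e.g. "indeterminate") becomes missing.
#' Samples with any missing required field are dropped with a message.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return list with elements `survival` ([survival_data]) and
#'   `covariates` (numeric matrix, 5 x samples, rows
#'   `CNB`, `TMB`, `Age`, `ER`, `PR`).
#' @export
read_clinical <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_months", "os_event", "age", "er", "pr",
            "cnb", "tmb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  df$er <- encode_receptor(df$er)
  df$pr <- encode_receptor(df$pr)
  num_cols <- c("os_months", "os_event", "age", "cnb", "tmb")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  keep <- stats::complete.cases(df[, need])
  n_drop <- sum(!keep)
  if (n_drop) message(sprintf("read_clinical: dropped %d sample(s) with missing fields", n_drop))
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no complete clinical records")
  surv <- survival_data(df$os_months, df$os_event, df$sample_id)
  cov <- rbind(CNB = df$cnb, TMB = df$tmb, Age = df$age,
               ER = df$er, PR = df$pr)
  colnames(cov) <- df$sample_id
  list(survival = surv, covariates = cov)
}

# 1 = positive, 0 = negative; anything else (indeterminate, blank) -> NA
encode_receptor <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[x %in% c("1", "positive", "pos", "+")] <- 1
  out[x %in% c("0", "negative", "neg", "-")] <- 0
  out
}

#' Bundle sample-aligned omics blocks with survival data
#'
#' An omics bundle holds named feature-by-sample blocks (eigengene
#' matrices and covariate groups) sharing one ordered set of sample ids,
#' plus the matching survival data.  Feature identifiers must be unique
#' across blocks so that features can be addressed globally (e.g. by the
#' ablation routines).
#'
#' @param blocks named list of numeric matrices (features x samples),
#'   each with rownames (feature ids) and colnames (sample ids).
#' @param survival a [survival_data] whose sample ids match the blocks.
#' @return list of class `omics_bundle` with elements `blocks`,
#'   `survival`, `sample_ids`.
#' @export
omics_bundle <- function(blocks, survival) {
  if (!length(blocks) || is.null(names(blocks)) || any(names(blocks) == ""))
    stop("`blocks` must be a non-empty named list")
  sids <- NULL
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.matrix(b) || !is.numeric(b))
      stop(sprintf("block '%s' must be a numeric matrix", nm))
    if (is.null(rownames(b)) || is.null(colnames(b)))
      stop(sprintf("block '%s' needs feature and sample names", nm))
    if (is.null(sids)) sids <- colnames(b)
    else if (!identical(colnames(b), sids))
      stop(sprintf("block '%s' sample ids differ from the first block", nm))
  }
  feats <- unlist(lapply(blocks, rownames), use.names = FALSE)
  check_unique_ids(feats, "feature (across blocks)")
  if (!inherits(survival, "survival_data"))
    stop("`survival` must be a survival_data object")
  if (!identical(survival$sample_id, sids))
    stop("survival sample ids must match block sample ids (same order)")
  structure(list(blocks = blocks, survival = survival, sample_ids = sids),
            class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("<omics_bundle> %d samples, %d events\n",
              length(x$sample_ids), sum(x$survival$event)))
  for (nm in names(x$blocks))
    cat(sprintf("  block %-12s %4d features\n", nm, nrow(x$blocks[[nm]])))
  invisible(x)
}

#' Number of Cox-layer input features in a bundle
#' @param bundle an [omics_bundle].
#' @return integer, total feature count across blocks.
#' @export
bundle_n_features <- function(bundle) {
  sum(vapply(bundle$blocks, nrow, integer(1)))
}

#' All feature identifiers of a bundle, block by block
#' @param bundle an [omics_bundle].
#' @return named character vector (names = owning block).
#' @export
bundle_feature_ids <- function(bundle) {
  out <- unlist(lapply(bundle$blocks, rownames), use.names = FALSE)
  names(out) <- rep(names(bundle$blocks),
                    vapply(bundle$blocks, nrow, integer(1)))
  out
}

#' Align sample-keyed blocks on their common samples
#'
#' Restricts every block (and the survival data) to the intersection of
#' sample ids, reordered lexicographically for determinism, and reports
#' how many samples each block lost.
#'
#' @param blocks named list of feature x sample matrices.
#' @param survival a [survival_data]; only its matching rows are kept.
#' @return an [omics_bundle] over the common samples.
#' @export
align_samples <- function(blocks, survival) {
  if (!length(blocks)) stop("need at least one block")
  common <- colnames(blocks[[1]])
  for (b in blocks) common <- intersect(common, colnames(b))
  common <- intersect(common, survival$sample_id)
  if (!length(common)) stop("empty sample intersection across blocks")
  common <- sort(common)
  dropped <- vapply(blocks, function(b) ncol(b) - length(common), numeric(1))
  if (any(dropped > 0))
    message("align_samples: dropped ",
            paste(sprintf("%s=%d", names(blocks), dropped), collapse = ", "),
            " sample(s)")
  blocks <- lapply(blocks, function(b) b[, common, drop = FALSE])
  si <- match(common, survival$sample_id)
  surv <- survival_data(survival$time[si], survival$event[si], common)
  omics_bundle(blocks, surv)
}

#' Subset an omics bundle by samples and/or features
#'
#' @param bundle an [omics_bundle].
#' @param samples sample indices or ids to keep (default all).
#' @param features feature ids to keep (default all); blocks left empty
#'   are removed.
#' @return an [omics_bundle].
#' @export
subset_bundle <- function(bundle, samples = NULL, features = NULL) {
  if (is.null(samples)) samples <- seq_along(bundle$sample_ids)
  if (is.character(samples)) samples <- match(samples, bundle$sample_ids)
  if (anyNA(samples)) stop("unknown sample id(s)")
  blocks <- lapply(bundle$blocks, function(b) b[, samples, drop = FALSE])
  if (!is.null(features)) {
    unknown <- setdiff(features, unlist(lapply(blocks, rownames)))
    if (length(unknown))
      stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
    blocks <- lapply(blocks, function(b)
      b[rownames(b) %in% features, , drop = FALSE])
    blocks <- blocks[vapply(blocks, nrow, integer(1)) > 0]
    if (!length(blocks)) stop("feature subset leaves no inputs")
  }
  surv <- bundle$survival[samples, , drop = FALSE]
  omics_bundle(blocks, survival_data(surv$time, surv$event, surv$sample_id))
}
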