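# Co-expression module mining: correlation network construction,
# spectral-style weight normalisation, lmQCM quasi-clique merging, and
# SVD eigengene summarisation of the mined modules.

#' Parameters for lmQCM module mining
#'
#' @param gamma seed-edge threshold (> 0).  With `seed_mode = "relative"`
#'   an edge seeds a new cluster when its weight is at least
#'   `gamma * max(weight)`.
#' @param lam density-decay scale (> 0); larger values tighten the
#'   density acceptance rule as clusters grow.
#' @param t density-decay offset (>= 0).
#' @param beta merge-overlap threshold in (0, 1]: clusters A, B merge
#'   when `|A intersect B| / min(|A|, |B|) >= beta`.
#' @param min_size minimum cluster size retained.
#' @param correlation `"spearman"` (default) or `"pearson"`.
#' @param seed_mode `"relative"` (threshold `gamma * max weight`, default)
#'   or `"absolute"` (threshold `gamma`).
#' @param seed_on scale of the seed test: `"raw"` (absolute correlation,
#'   default — the published gamma values are correlation-scale) or
#'   `"normalized"` (the degree-normalised weights used for expansion).
#' @param density_mode `"relative"` (accept a new vertex while the new
#'   density stays above `alpha_n` times the current density, default) or
#'   `"absolute"` (above `alpha_n` itself), with
#'   `alpha_n = 1 - 1 / (2 * lam * (n + t))` for current size n.
#' @return list of class `lmqcm_params`.
#' @export
lmqcm_params <- function(gamma = 0.7, lam = 1, t = 1, beta = 0.4,
                         min_size = 10,
                         correlation = c("spearman", "pearson"),
                         seed_mode = c("relative", "absolute"),
                         density_mode = c("relative", "absolute"),
                         seed_on = c("raw", "normalized")) {
  correlation <- match.arg(correlation)
  seed_mode <- match.arg(seed_mode)
  density_mode <- match.arg(density_mode)
  seed_on <- match.arg(seed_on)
  stopifnot(gamma > 0, lam > 0, t >= 0, beta > 0, beta <= 1, min_size >= 1)
  structure(list(gamma = gamma, lam = lam, t = t, beta = beta,
                 min_size = as.integer(min_size), correlation = correlation,
                 seed_mode = seed_mode, density_mode = density_mode,
                 seed_on = seed_on),
            class = "lmqcm_params")
}

#' Feature-feature correlation matrix
#'
#' Spearman (average ranks for ties) or Pearson correlation between the
#' rows of an expression matrix.  Features with zero variance cannot be
#' ranked; their correlations are set to 0 with a warning.
#'
#' @param expr an [expression_matrix] with >= 3 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (ncol(expr) < 3) stop("need at least 3 samples for correlations")
  const <- row_vars(unclass(expr)) == 0
  cm <- suppressWarnings(stats::cor(t(unclass(expr)), method = method))
  if (any(const)) {
    warning(sprintf("%d zero-variance feature(s); correlations set to 0",
                    sum(const)))
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm
}

#' Spectral-style normalised edge weights from a correlation matrix
#'
#' Takes absolute off-diagonal correlations as raw edge weights and
#' normalises them by the degree product, `w_ij / sqrt(d_i * d_j)` with
#' `d_i = sum_k w_ik` — the normalisation used in spectral clustering.
#' Isolated vertices (zero degree) keep zero-weight edges.
#'
#' @param corr symmetric correlation matrix.
#' @return symmetric non-negative weight matrix with zero diagonal.
#' @export
lmqcm_weights <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  w <- abs(corr)
  diag(w) <- 0
  d <- rowSums(w)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  raw <- w
  w <- w * tcrossprod(inv)
  # enforce exact symmetry against floating-point drift
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(corr)
  attr(w, "raw_weights") <- raw   # pre-normalisation weights for seeding
  w
}

#' Mine co-expression modules by local maximal quasi-clique merging
#'
#' Greedy lmQCM procedure on a weighted feature graph:
#' \enumerate{
#'   \item edges are visited by descending weight; an edge whose weight
#'     reaches the seed threshold and whose endpoints are not yet part of
#'     any cluster seeds a new cluster;
#'   \item the cluster greedily absorbs the outside vertex with maximal
#'     total connection while the density
#'     `2 * sum(internal weights) / (n * (n - 1))` stays above the decay
#'     bound controlled by `lam` and `t` (see [lmqcm_params]);
#'   \item clusters whose overlap ratio reaches `beta` are merged,
#'     highest-overlap pair first, to a fixed point;
#'   \item clusters smaller than `min_size` are dropped and the survivors
#'     are returned sorted by size, descending (ties by first feature id).
#' }
#' Overlap between returned modules is allowed.
#'
#' @param weights symmetric non-negative weight matrix, zero diagonal,
#'   with feature rownames.
#' @param params an [lmqcm_params].
#' @param source free-text label recorded with the result (e.g. the
#'   omics block name).
#' @return list of class `module_set` with elements `modules` (list of
#'   character vectors of feature ids), `params`, `source`.
#' @export
lmqcm_mine <- function(weights, params = lmqcm_params(), source = "") {
  if (!isSymmetric(unname(weights), tol = 1e-8))
    stop("weight matrix must be symmetric")
  if (any(weights < 0)) stop("weights must be non-negative")
  n <- nrow(weights)
  ids <- rownames(weights)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  diag(weights) <- 0

  # seed test runs on raw |correlation| weights when available (the
  # published gamma values are correlation-scale); expansion always uses
  # the degree-normalised weights
  seed_w <- if (params$seed_on == "raw" &&
                !is.null(attr(weights, "raw_weights")))
    attr(weights, "raw_weights") else weights
  ut <- which(upper.tri(weights) & seed_w > 0, arr.ind = TRUE)
  clusters <- list()
  if (nrow(ut)) {
    ew <- seed_w[ut]
    wmax <- max(ew)
    thr <- if (params$seed_mode == "relative") params$gamma * wmax
           else params$gamma
    ord <- order(-ew, ut[, 1], ut[, 2])
    absorbed <- logical(n)
    for (e in ord) {
      if (ew[e] < thr) break
      i <- ut[e, 1]; j <- ut[e, 2]
      if (absorbed[i] || absorbed[j]) next
      cl <- expand_cluster(weights, c(i, j), params)
      absorbed[cl] <- TRUE
      clusters[[length(clusters) + 1L]] <- sort(cl)
    }
  }
  clusters <- merge_clusters(clusters, params$beta)
  clusters <- clusters[vapply(clusters, length, integer(1)) >= params$min_size]
  modules <- lapply(clusters, function(cl) ids[cl])
  if (length(modules)) {
    first_id <- vapply(modules, function(m) sort(m)[1], character(1))
    modules <- modules[order(-vapply(modules, length, integer(1)), first_id)]
  }
  structure(list(modules = modules, params = params, source = source),
            class = "module_set")
}

# Greedy density-constrained expansion of a seeded vertex pair.
expand_cluster <- function(weights, members, params) {
  conn <- colSums(weights[members, , drop = FALSE])
  internal <- weights[members[1], members[2]]
  conn[members] <- -Inf
  repeat {
    nc <- length(members)
    v <- which.max(conn)
    cw <- conn[v]
    if (!is.finite(cw) || cw <= 0) break
    d_cur <- 2 * internal / (nc * (nc - 1))
    d_new <- 2 * (internal + cw) / ((nc + 1) * nc)
    alpha <- 1 - 1 / (2 * params$lam * (nc + params$t))
    bound <- if (params$density_mode == "relative") alpha * d_cur else alpha
    if (d_new < bound) break
    members <- c(members, v)
    internal <- internal + cw
    conn <- conn + weights[v, ]
    conn[v] <- -Inf
  }
  members
}

# Merge clusters with overlap ratio >= beta, highest ratio first,
# iterating to a fixed point.
merge_clusters <- function(clusters, beta) {
  repeat {
    k <- length(clusters)
    if (k < 2) return(clusters)
    best <- c(0, 0); best_r <- -1
    for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
      ov <- length(intersect(clusters[[a]], clusters[[b]]))
      r <- ov / min(length(clusters[[a]]), length(clusters[[b]]))
      if (r > best_r) { best_r <- r; best <- c(a, b) }
    }
    if (best_r < beta) return(clusters)
    merged <- sort(union(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  cat(sprintf("<module_set> %d module(s)%s\n", length(sizes),
              if (length(sizes)) paste0(", sizes ",
                                        paste(sizes, collapse = ", "))
              else ""))
  invisible(x)
}

#' Number of modules in a module set
#' @param x a `module_set`.
#' @export
n_modules <- function(x) length(x$modules)

#' Eigengene of one co-expression module
#'
#' Summarises a module into its first principal component across
#' samples: each member gene is z-scored (mean 0, unit variance across
#' samples), and the first right-singular vector of the standardised
#' submatrix is returned.  The sign is fixed so the eigengene correlates
#' non-negatively with the module's mean (standardised) expression
#' profile; the vector has unit Euclidean norm.
#'
#' @param expr an [expression_matrix].
#' @param module character vector of >= 2 feature ids present in `expr`.
#' @return numeric vector over samples (unit norm), with attribute
#'   `explained_variance` — the fraction of total variance captured.
#' @export
eigengene <- function(expr, module) {
  if (length(module) < 2) stop("a module needs at least 2 features")
  missing <- setdiff(module, rownames(expr))
  if (length(missing))
    stop("module feature(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- unclass(expr)[module, , drop = FALSE]
  z <- standardize_rows(sub)
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  ref <- colMeans(z)
  if (sum(v * ref) < 0) v <- -v
  ev <- sv$d[1]^2 / sum(sv$d^2)
  names(v) <- colnames(expr)
  attr(v, "explained_variance") <- ev
  v
}

standardize_rows <- function(m) {
  ctr <- m - rowMeans(m)
  s <- sqrt(rowSums(ctr * ctr) / (ncol(m) - 1))
  s[s == 0] <- 1   # constant rows stay all-zero after centering
  ctr / s
}

#' Eigengene matrix of a module set
#'
#' Stacks [eigengene] vectors, one row per mined module, preserving the
#' module order of `modules`.
#'
#' @param expr an [expression_matrix].
#' @param modules a `module_set` from [lmqcm_mine].
#' @param prefix row-name prefix for module ids (default `"M"`).
#' @return An [expression_matrix] (modules x samples); zero rows when
#'   the module set is empty.
#' @export
eigengene_matrix <- function(expr, modules, prefix = "M") {
  k <- n_modules(modules)
  out <- matrix(0, k, ncol(expr),
                dimnames = list(if (k) paste0(prefix, seq_len(k)),
                                colnames(expr)))
  for (m in seq_len(k))
    out[m, ] <- eigengene(expr, modules$modules[[m]])
  if (!k) return(out)
  expression_matrix(out)
}

#' Serialise a module set to JSON
#' @param modules a `module_set`.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  jsonlite::write_json(list(params = unclass(modules$params),
                            source = modules$source,
                            modules = modules$modules),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
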