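test_that("spearman correlations match hand-ranked values", {
  m <- toy_expr(rbind(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3),
                      up = c(0.1, 5, 7, 9), dn = c(9, 7, 5, 0.1)))
  cm <- correlation_matrix(m, "spearman")
  expect_equal(cm["x", "y"], 0.6)            # 1 - 6*4 / (4*15)
  expect_equal(cm["x", "up"], 1)             # both strictly increasing
  expect_equal(cm["up", "dn"], -1)           # profile vs its negation
  expect_true(isSymmetric(cm))
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
})

test_that("zero-variance features get zero correlations with a warning", {
  m <- toy_expr(rbind(a = c(1, 2, 3), flat = c(5, 5, 5)))
  expect_warning(cm <- correlation_matrix(m), "zero-variance")
  expect_equal(cm["flat", "a"], 0)
  expect_equal(cm["flat", "flat"], 1)
  expect_error(correlation_matrix(toy_expr(matrix(1:4, 2, 2))), "3 samples")
})

test_that("weight normalisation matches hand-computed D^-1/2 W D^-1/2", {
  # 2 nodes: the single edge normalises to exactly 1
  c2 <- matrix(c(1, .37, .37, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(lmqcm_weights(c2)["a", "b"], 1)

  # 3-node toy with |corr| = {ab .9, ac .6, bc .3}
  c3 <- diag(3)
  c3[1, 2] <- c3[2, 1] <- -0.9
  c3[1, 3] <- c3[3, 1] <- 0.6
  c3[2, 3] <- c3[3, 2] <- 0.3
  dimnames(c3) <- list(letters[1:3], letters[1:3])
  w <- lmqcm_weights(c3)
  d <- c(1.5, 1.2, 0.9)
  expect_equal(w["a", "b"], 0.9 / sqrt(d[1] * d[2]))
  expect_equal(w["a", "c"], 0.6 / sqrt(d[1] * d[3]))
  expect_equal(w["b", "c"], 0.3 / sqrt(d[2] * d[3]))
  expect_equal(diag(w), rep(0, 3), ignore_attr = TRUE)

  # all-zero correlations -> all-zero weights, isolated vertices kept at 0
  z <- diag(3); dimnames(z) <- dimnames(c3)
  expect_true(all(lmqcm_weights(z) == 0))
})

planted_two_blocks <- function(n_samples = 60, seed = 1, noise = 0.25) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  vals <- rbind(
    t(sapply(1:12, function(i) f1 + rnorm(n_samples, sd = noise))),
    t(sapply(1:12, function(i) f2 + rnorm(n_samples, sd = noise))),
    matrix(rnorm(10 * n_samples), 10))
  toy_expr(vals)
}

test_that("mining recovers two planted blocks and respects size filter", {
  m <- planted_two_blocks()
  w <- lmqcm_weights(correlation_matrix(m))
  ms <- lmqcm_mine(w, lmqcm_params(min_size = 10), source = "toy")
  expect_equal(n_modules(ms), 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  blocks <- list(paste0("g", 1:12), paste0("g", 13:24))
  best <- sapply(blocks, function(bl)
    max(sapply(ms$modules, jac, b = bl)))
  expect_true(all(best >= 0.9))

  # identity correlation: no off-diagonal signal -> no modules
  idm <- diag(20)
  dimnames(idm) <- list(paste0("g", 1:20), paste0("g", 1:20))
  expect_equal(n_modules(lmqcm_mine(lmqcm_weights(idm), lmqcm_params())), 0)

  # min_size larger than any block -> empty set
  ms2 <- lmqcm_mine(w, lmqcm_params(min_size = 20))
  expect_equal(n_modules(ms2), 0)
})

test_that("mined modules are invariant to input gene order", {
  m <- planted_two_blocks(seed = 3)
  w1 <- lmqcm_weights(correlation_matrix(m))
  set.seed(99)
  perm <- sample(nrow(m))
  mp <- expression_matrix(unclass(m)[perm, , drop = FALSE])
  w2 <- lmqcm_weights(correlation_matrix(mp))
  s1 <- lapply(lmqcm_mine(w1, lmqcm_params())$modules, sort)
  s2 <- lapply(lmqcm_mine(w2, lmqcm_params())$modules, sort)
  expect_setequal(sapply(s1, paste, collapse = ","),
                  sapply(s2, paste, collapse = ","))
})

test_that("cluster merging honours the overlap threshold", {
  cl <- list(1:10, c(1:6, 11:14), 21:30)
  # overlap 6 / min(10, 10) = 0.6
  merged <- eigensurv:::merge_clusters(cl, beta = 0.6)
  expect_equal(length(merged), 2)
  expect_true(any(sapply(merged, function(x) setequal(x, c(1:14)))))
  kept <- eigensurv:::merge_clusters(cl, beta = 0.7)
  expect_equal(length(kept), 3)
})

test_that("eigengene matches an independent eigendecomposition oracle", {
  set.seed(11)
  m <- toy_expr(matrix(rnorm(40), 5, 8))
  v <- eigengene(m, paste0("g", 1:5))
  z <- t(scale(t(unclass(m))))             # row-standardised
  ev <- eigen(crossprod(z), symmetric = TRUE)$vectors[, 1]
  if (sum(ev * v) < 0) ev <- -ev
  expect_equal(unname(as.vector(v)), unname(ev), tolerance = 1e-10)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("eigengene sign and rank-1 conventions hold", {
  set.seed(2)
  f <- rnorm(10)
  m <- toy_expr(rbind(f, f, f), genes = paste0("g", 1:3))
  v <- eigengene(m, c("g1", "g2", "g3"))
  expect_equal(attr(v, "explained_variance"), 1, tolerance = 1e-12)
  expect_equal(abs(cor(as.vector(v), f)), 1, tolerance = 1e-10)

  # negating all member genes leaves corr(eigengene, mean profile) >= 0
  mn <- toy_expr(-rbind(f, f + rnorm(10, sd = .1), f),
                 genes = paste0("g", 1:3))
  vn <- eigengene(mn, c("g1", "g2", "g3"))
  zr <- eigensurv:::standardize_rows(unclass(mn))
  expect_gte(cor(as.vector(vn), colMeans(zr)), 0)

  expect_error(eigengene(m, c("g1", "gX")), "gX")
  expect_error(eigengene(m, "g1"), "at least 2")
})

test_that("eigengene variance fraction dominates random unit probes", {
  set.seed(4)
  m <- toy_expr(matrix(rnorm(9 * 14), 9, 14))
  v <- eigengene(m, rownames(m))
  z <- eigensurv:::standardize_rows(unclass(m))
  ev <- attr(v, "explained_variance")
  tot <- sum(z^2)
  for (k in 1:25) {
    u <- rnorm(ncol(z)); u <- u / sqrt(sum(u^2))
    expect_lte(sum((z %*% u)^2) / tot, ev + 1e-12)
  }
})

test_that("eigengene_matrix stacks modules in order and recovers factors", {
  co <- generate_cohort(synthetic_spec(
    n_samples = 120, n_genes = 60,
    module_plan = data.frame(size = c(15, 15), loading = 1, noise_sd = 0.4),
    n_mirna = 0,
    mirna_module_plan = data.frame(size = integer(0), loading = numeric(0),
                                   noise_sd = numeric(0)),
    factor_coefs = c(0, 0), seed = 8))
  ms <- lmqcm_mine(lmqcm_weights(correlation_matrix(co$mrna)),
                   lmqcm_params(min_size = 10))
  em <- eigengene_matrix(co$mrna, ms)
  expect_equal(nrow(em), n_modules(ms))
  expect_equal(rowSums(unclass(em)^2), rep(1, nrow(em)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # each planted factor is tracked by some eigengene row
  for (k in 1:2) {
    cors <- apply(unclass(em), 1, function(r)
      abs(cor(r, co$truth$factors[k, ])))
    expect_gt(max(cors), 0.95)
  }
  # empty module set -> 0-row matrix
  idm <- diag(3)
  dimnames(idm) <- list(paste0("g", 1:3), paste0("g", 1:3))
  none <- lmqcm_mine(lmqcm_weights(idm), lmqcm_params())
  expect_equal(nrow(eigengene_matrix(co$mrna[1:3, ], none)), 0)
})
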