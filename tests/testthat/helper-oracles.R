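# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive brute-force formulations so they stay
# independent of the vectorised implementation paths they check.

# O(n^2) double-loop concordance index: a pair (i, j) is usable iff
# time[i] < time[j] and sample i carries an event; concordant when the
# earlier sample has the higher risk; risk ties count 1/2.
oracle_cindex <- function(risk, time, event) {
  conc <- 0; tied <- 0; usable <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      usable <- usable + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / usable
}

# direct evaluation of the negative log partial likelihood by explicit
# risk-set enumeration (Breslow: tied events share the full risk set)
oracle_nll <- function(eta, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    s <- s + log(sum(exp(eta[rs]))) - eta[i]
  }
  s
}

# hand-tabulated two-group log-rank arithmetic (explicit per-event-time
# hypergeometric moments)
oracle_logrank_chisq <- function(time, event, grp) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n_a <- sum(at & grp == 0)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 0)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# tiny expression fixture with named rows/columns
toy_expr <- function(values, genes = rownames(as.matrix(values)),
                     samples = colnames(as.matrix(values))) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, genes, samples)
}

# linear proportional-hazards cohort at the eigengene level: features
# are iid standard normal, eta = beta %*% X, exponential baseline,
# uniform censoring solved to hit the target fraction
make_linear_cohort <- function(n, beta, censoring = 0.3, seed = 1,
                               h0 = 0.02, feature_prefix = "E",
                               block = "mrna") {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(stats::rnorm(p * n), p, n,
              dimnames = list(paste0(feature_prefix, seq_len(p)),
                              sprintf("S%04d", seq_len(n))))
  eta <- drop(beta %*% X)
  T_event <- -log(stats::runif(n)) / (h0 * exp(eta))
  horizon <- eigensurv:::censor_horizon(T_event, censoring)
  C <- stats::runif(n, 0, horizon)
  surv <- survival_data(pmin(T_event, C), as.integer(T_event <= C),
                        colnames(X))
  blocks <- list(X)
  names(blocks) <- block
  list(bundle = omics_bundle(blocks, surv), eta = eta, X = X)
}

# random censored survival instance for pairwise-metric tests
random_surv <- function(n, seed, cens = 0.3) {
  set.seed(seed)
  tt <- stats::rexp(n, 0.1)
  cc <- stats::quantile(tt, 1 - cens) * stats::runif(n)
  list(risk = stats::rnorm(n), time = pmin(tt, cc),
       event = as.integer(tt <= cc))
}
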