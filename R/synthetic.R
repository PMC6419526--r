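# Seeded synthetic multi-omics survival cohorts with known ground
# truth: block-correlated expression driven by latent module factors,
# independent scalar covariates shaped like a breast-cancer cohort, and
# proportional-hazards event times with independent uniform censoring.

#' Specification of a synthetic cohort
#'
#' Defaults mimic the shape of a 583-patient breast-cancer cohort:
#' diagnosis age uniform on 26-90, ER positivity 76.16%, PR positivity
#' 67.41%, exponential baseline hazard giving a median survival of about
#' 31.7 months at zero linear predictor, and a 30% censoring target.
#' Expression defaults are desk-scale (hundreds of genes, not the full
#' 13k-gene transcriptome) so that correlation matrices stay small.
#'
#' @param n_samples cohort size (default 583).
#' @param n_genes total mRNA features including background noise genes
#'   (default 600).
#' @param module_plan data frame with columns `size`, `loading`,
#'   `noise_sd`: each row plants one co-expression module whose member
#'   genes are `loading * factor + Normal(0, noise_sd)` around a shared
#'   standard-normal latent factor.
#' @param n_mirna total miRNA features (0 disables the block).
#' @param mirna_module_plan module plan for the miRNA block.
#' @param factor_coefs log-hazard coefficient per latent factor (mRNA
#'   factors first, then miRNA factors); recycled with zeros.
#' @param covariate_coefs named log-hazard coefficients for
#'   `CNB`, `TMB`, `Age`, `ER`, `PR` (applied to the raw covariate).
#' @param baseline_hazard exponential baseline rate (events/month).
#' @param censoring target censored fraction in (0, 1).
#' @param er_prob,pr_prob receptor positivity probabilities.
#' @param age_range closed range of diagnosis ages.
#' @param seed integer seed; generation is fully reproducible.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 583, n_genes = 600,
                           module_plan = data.frame(size = c(30, 30, 25, 25, 20),
                                                    loading = 1,
                                                    noise_sd = 0.5),
                           n_mirna = 80,
                           mirna_module_plan = data.frame(size = c(8, 6),
                                                          loading = 1,
                                                          noise_sd = 0.5),
                           factor_coefs = c(0.8, -0.5),
                           covariate_coefs = c(CNB = 0, TMB = 0, Age = 0.02,
                                               ER = -0.5, PR = -0.3),
                           baseline_hazard = log(2) / 31.7,
                           censoring = 0.3,
                           er_prob = 0.7616, pr_prob = 0.6741,
                           age_range = c(26, 90), seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 1,
            all(module_plan$size >= 2), sum(module_plan$size) <= n_genes,
            censoring > 0, censoring < 1, baseline_hazard > 0)
  if (n_mirna > 0) stopifnot(sum(mirna_module_plan$size) <= n_mirna)
  n_fac <- nrow(module_plan) + if (n_mirna > 0) nrow(mirna_module_plan) else 0
  factor_coefs <- c(factor_coefs, numeric(n_fac))[seq_len(n_fac)]
  need_cov <- c("CNB", "TMB", "Age", "ER", "PR")
  cc <- stats::setNames(numeric(5), need_cov)
  cc[intersect(names(covariate_coefs), need_cov)] <-
    covariate_coefs[intersect(names(covariate_coefs), need_cov)]
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 module_plan = module_plan, n_mirna = as.integer(n_mirna),
                 mirna_module_plan = mirna_module_plan,
                 factor_coefs = factor_coefs, covariate_coefs = cc,
                 baseline_hazard = baseline_hazard, censoring = censoring,
                 er_prob = er_prob, pr_prob = pr_prob,
                 age_range = age_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# plant one expression block: modules first (consecutive genes), then
# pure-noise background; returns the matrix, factors, and membership
plant_block <- function(n_genes, plan, n, prefix) {
  k <- nrow(plan)
  vals <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  factors <- matrix(0, k, n)
  membership <- vector("list", k)
  g <- 0L
  for (m in seq_len(k)) {
    f <- stats::rnorm(n)
    factors[m, ] <- f
    rows <- g + seq_len(plan$size[m])
    noise <- matrix(stats::rnorm(plan$size[m] * n, sd = plan$noise_sd[m]),
                    plan$size[m], n)
    vals[rows, ] <- plan$loading[m] * rep(f, each = plan$size[m]) + noise
    membership[[m]] <- paste0(prefix, rows)
    g <- g + plan$size[m]
  }
  rownames(vals) <- paste0(prefix, seq_len(n_genes))
  if (k) rownames(factors) <- paste0("F_", prefix, seq_len(k))
  list(values = vals, factors = factors, membership = membership)
}

#' Generate a synthetic multi-omics survival cohort
#'
#' Latent module factors are standard normal per sample; member genes
#' are noisy copies of their factor; background genes are pure noise.
#' Event times follow a proportional-hazards law by inverse transform,
#' `T = -log(U) / (h0 * exp(eta))` with
#' `eta = sum(coef * factor) + sum(coef * covariate)`; censoring times
#' are uniform on `(0, m)` with the horizon `m` solved so that the
#' expected censored fraction matches `spec$censoring`.
#'
#' @param spec a [synthetic_spec].
#' @return list of class `synthetic_cohort`: `mrna`, `mirna`
#'   ([expression_matrix] or `NULL`), `covariates` (5 x n matrix),
#'   `survival` ([survival_data]), and `truth` (factors, memberships,
#'   `eta`, coefficients, censor horizon, achieved censoring fraction).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sids <- sprintf("S%03d", seq_len(n))

  mr <- plant_block(spec$n_genes, spec$module_plan, n, "g")
  mi <- if (spec$n_mirna > 0)
    plant_block(spec$n_mirna, spec$mirna_module_plan, n, "mir") else NULL

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  er <- stats::rbinom(n, 1, spec$er_prob)
  pr <- stats::rbinom(n, 1, spec$pr_prob)
  cnb <- stats::rlnorm(n, meanlog = 8, sdlog = 1)
  tmb <- stats::rlnorm(n, meanlog = 3.5, sdlog = 0.8)
  cov <- rbind(CNB = cnb, TMB = tmb, Age = age, ER = er, PR = pr)
  colnames(cov) <- sids

  factors <- rbind(mr$factors, if (!is.null(mi)) mi$factors)
  eta <- drop(spec$factor_coefs %*% factors) +
    drop(spec$covariate_coefs %*% cov)
  T_event <- -log(stats::runif(n)) / (spec$baseline_hazard * exp(eta))

  horizon <- censor_horizon(T_event, spec$censoring)
  C <- stats::runif(n, 0, horizon)
  event <- as.integer(T_event <= C)
  time <- pmin(T_event, C)
  achieved <- mean(event == 0)
  if (abs(achieved - spec$censoring) > 0.1)
    warning(sprintf("achieved censoring %.2f far from target %.2f",
                    achieved, spec$censoring))

  colnames(mr$values) <- sids
  if (!is.null(mi)) colnames(mi$values) <- sids
  if (!is.null(factors)) colnames(factors) <- sids
  structure(list(
    mrna = expression_matrix(mr$values),
    mirna = if (!is.null(mi)) expression_matrix(mi$values),
    covariates = cov,
    survival = survival_data(time, event, sids),
    truth = list(factors = factors,
                 mrna_membership = mr$membership,
                 mirna_membership = if (!is.null(mi)) mi$membership,
                 eta = stats::setNames(eta, sids),
                 factor_coefs = spec$factor_coefs,
                 covariate_coefs = spec$covariate_coefs,
                 event_time = T_event, censor_horizon = horizon,
                 achieved_censoring = achieved),
    spec = spec), class = "synthetic_cohort")
}

# horizon m of Uniform(0, m) censoring such that the expected censored
# fraction mean_i P(C < T_i) = mean_i min(T_i / m, 1) hits the target
censor_horizon <- function(T_event, target) {
  f <- function(m) mean(pmin(T_event / m, 1)) - target
  hi <- max(T_event) / target  # f(hi) <= mean(T)/hi*... < target region
  lo <- min(T_event) * 1e-6
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d events (%.0f%% censored)\n",
              length(x$survival$sample_id), sum(x$survival$event),
              100 * x$truth$achieved_censoring))
  invisible(x)
}

#' Ground-truth bundle of a synthetic cohort
#'
#' Builds an [omics_bundle] whose expression blocks are the true latent
#' factors (bypassing module mining), for tests that isolate the
#' network-training stage from the co-expression stage.
#'
#' @param cohort a `synthetic_cohort`.
#' @param include_covariates add `cnb_tmb` and `clinical` blocks
#'   (default `TRUE`).
#' @return an [omics_bundle] with block `mrna` (and `mirna`,
#'   `cnb_tmb`, `clinical` as available).
#' @export
bundle_from_truth <- function(cohort, include_covariates = TRUE) {
  k_mr <- nrow(cohort$spec$module_plan)
  blocks <- list(mrna = cohort$truth$factors[seq_len(k_mr), , drop = FALSE])
  if (!is.null(cohort$mirna)) {
    blocks$mirna <- cohort$truth$factors[-seq_len(k_mr), , drop = FALSE]
  }
  if (include_covariates) {
    blocks$cnb_tmb <- cohort$covariates[c("CNB", "TMB"), , drop = FALSE]
    blocks$clinical <- cohort$covariates[c("Age", "ER", "PR"), , drop = FALSE]
  }
  omics_bundle(blocks, cohort$survival)
}

#' Deterministic 12-sample worked-example cohort
#'
#' A tiny fixed cohort (12 samples, 40 genes, two planted 12-gene
#' modules with low noise, no miRNA block) used across documentation
#' examples and golden-output tests.  Regeneration is byte-identical:
#' the seed is fixed internally.
#'
#' @return a `synthetic_cohort`.
#' @export
worked_example_cohort <- function() {
  generate_cohort(synthetic_spec(
    n_samples = 12, n_genes = 40,
    module_plan = data.frame(size = c(12, 12), loading = 1,
                             noise_sd = 0.1),
    n_mirna = 0, mirna_module_plan = data.frame(size = integer(0),
                                                loading = numeric(0),
                                                noise_sd = numeric(0)),
    factor_coefs = c(1.5, 0),
    covariate_coefs = c(Age = 0, ER = 0, PR = 0),
    censoring = 0.25, seed = 42))
}

#' Write a synthetic cohort to a directory of delimited files
#'
#' Emits the same on-disk formats the real pipeline reads (`mrna.tsv`,
#' `mirna.tsv`, `clinical.tsv`) plus `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$mrna, file.path(dir, "mrna.tsv"))
  if (!is.null(cohort$mirna))
    write_expression(cohort$mirna, file.path(dir, "mirna.tsv"))
  cl <- data.frame(sample_id = cohort$survival$sample_id,
                   os_months = cohort$survival$time,
                   os_event = cohort$survival$event,
                   age = cohort$covariates["Age", ],
                   er = cohort$covariates["ER", ],
                   pr = cohort$covariates["PR", ],
                   cnb = cohort$covariates["CNB", ],
                   tmb = cohort$covariates["TMB", ])
  utils::write.table(cl, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(factor_coefs = cohort$truth$factor_coefs,
         covariate_coefs = as.list(cohort$truth$covariate_coefs),
         mrna_membership = cohort$truth$mrna_membership,
         mirna_membership = cohort$truth$mirna_membership,
         eta = as.list(cohort$truth$eta),
         achieved_censoring = cohort$truth$achieved_censoring),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
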