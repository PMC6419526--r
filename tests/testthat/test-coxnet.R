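test_that("sigmoid is exact, symmetric, and overflow-safe", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.7, -0.1, 2.2, 15)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 4), tolerance = 1e-15)
  expect_equal(sigmoid(50), 1, tolerance = 1e-15)
  expect_equal(sigmoid(-750), 0)         # no overflow/NaN far in the tail
  expect_false(any(is.nan(sigmoid(c(-1000, 1000)))))
})

paper_arch <- function(mrna = 57, mirna = 12) {
  cox_architecture(list(cox_branch("mrna", mrna, 8),
                        cox_branch("mirna", mirna, 4),
                        cox_branch("covariates", 5)))
}

test_that("weight counting reproduces the published arithmetic", {
  expect_identical(count_trainable_weights(paper_arch()), 521L)
  expect_identical(count_trainable_weights(paper_arch(13132, 530)), 107193L)
  # biases add one per hidden/output unit
  expect_identical(count_trainable_weights(paper_arch(), include_bias = TRUE),
                   521L + 8L + 4L + 1L)
  one <- cox_architecture(list(cox_branch("x", 1, 1)))
  expect_identical(count_trainable_weights(one), 2L)
})

test_that("forward pass matches hand evaluation and is per-sample", {
  lc <- make_linear_cohort(6, c(0.5, -0.25), seed = 2)
  arch <- cox_architecture(list(cox_branch("mrna", 2, 2)))
  cfg <- train_config(epochs = 1, seed = 1, scale_inputs = FALSE)
  m <- train_coxnet(lc$bundle, arch, cfg)

  # hand-composed: h = sigmoid(W x + bh); eta = beta . h + b0
  x <- lc$bundle$blocks$mrna[, 3]
  h <- sigmoid(m$params$W_mrna %*% x + m$params$bh_mrna)
  eta <- sum(m$params$beta * h) + m$params$b0
  expect_equal(unname(forward(m, lc$bundle, type = "lp")[3]),
               unname(drop(eta)), tolerance = 1e-12)
  expect_equal(unname(forward(m, lc$bundle)[3]),
               unname(drop(sigmoid(eta))), tolerance = 1e-12)

  # all-zero parameters: every risk is exactly 0.5
  z <- m
  z$params <- lapply(z$params, function(p) p * 0)
  expect_equal(unname(forward(z, lc$bundle)), rep(0.5, 6))

  # permuting samples permutes outputs identically
  perm <- c(4, 1, 6, 2, 5, 3)
  bp <- subset_bundle(lc$bundle, samples = perm)
  expect_equal(forward(m, bp), forward(m, lc$bundle)[perm])

  # dimension mismatch names the offending branch
  bad <- lc$bundle
  bad$blocks$mrna <- bad$blocks$mrna[1, , drop = FALSE]
  expect_error(forward(m, bad), "mrna")
})

test_that("partial likelihood matches direct evaluation and Breslow ties", {
  expect_equal(neg_log_partial_likelihood(c(0, 0, 0), c(1, 2, 3),
                                          c(1, 1, 1)), log(6))
  expect_equal(neg_log_partial_likelihood(c(0, 0), c(1, 2), c(1, 0)),
               log(2))
  expect_warning(v <- neg_log_partial_likelihood(c(1, 2), c(1, 2),
                                                 c(0, 0)), "no events")
  expect_equal(v, 0)

  # random instances against the explicit risk-set oracle, with ties
  for (seed in 1:6) {
    set.seed(seed)
    n <- 17
    eta <- rnorm(n)
    time <- sample(1:8, n, replace = TRUE)     # forces ties
    event <- rbinom(n, 1, 0.6)
    if (!any(event == 1)) event[1] <- 1
    expect_equal(neg_log_partial_likelihood(eta, time, event),
                 oracle_nll(eta, time, event), tolerance = 1e-10)
    # shift invariance to 1e-10
    expect_equal(neg_log_partial_likelihood(eta + 37.5, time, event),
                 neg_log_partial_likelihood(eta, time, event),
                 tolerance = 1e-10)
  }
})

test_that("analytic objective gradient matches central differences", {
  lc <- make_linear_cohort(5, c(0.8, -0.4), censoring = 0.2, seed = 9)
  arch <- cox_architecture(list(cox_branch("mrna", 2, 2)))
  m <- train_coxnet(lc$bundle, arch,
                    train_config(epochs = 2, full_batch = TRUE, seed = 3))
  gr <- eigensurv:::objective_gradient(m, lc$bundle)
  h <- 1e-6
  worst <- 0
  for (nm in names(m$params)) {
    for (i in seq_along(m$params[[nm]])) {
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + h
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - h
      fd <- (objective(up, lc$bundle) - objective(dn, lc$bundle)) / (2 * h)
      worst <- max(worst, abs(fd - gr[[nm]][i]))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("objective reduces to the likelihood when unpenalised", {
  lc <- make_linear_cohort(20, c(1), seed = 4)
  m <- train_coxnet(lc$bundle, cox_architecture(list(cox_branch("mrna", 1))),
                    train_config(epochs = 3, seed = 1))
  eta <- forward(m, lc$bundle, type = "lp")
  expect_equal(objective(m, lc$bundle, l1_lambda = 0),
               neg_log_partial_likelihood(eta, lc$bundle$survival$time,
                                          lc$bundle$survival$event))
  expect_gt(objective(m, lc$bundle, l1_lambda = 1),
            objective(m, lc$bundle, l1_lambda = 0))
})

test_that("training is seed-deterministic with a sane loss trace", {
  lc <- make_linear_cohort(80, c(1.2, 0, 0), censoring = 0.3, seed = 6)
  cfg <- train_config(epochs = 30, batch_size = 32, seed = 11)
  m1 <- train_coxnet(lc$bundle, config = cfg)
  m2 <- train_coxnet(lc$bundle, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$trace)))
  expect_lte(m1$trace[length(m1$trace)], m1$trace[1])
  expect_error(train_coxnet(lc$bundle, config = train_config(epochs = 5,
                                                             learning_rate = 1e6)),
               "learning rate")
})

test_that("degenerate linear model approaches the Newton-Raphson Cox fit", {
  skip_if_not_installed("survival")
  lc <- make_linear_cohort(300, c(1.0, -0.5), censoring = 0.3, seed = 13)
  arch <- cox_architecture(list(cox_branch("mrna", 2)), use_bias = FALSE)
  m <- train_coxnet(lc$bundle, arch,
                    train_config(epochs = 250, full_batch = TRUE,
                                 learning_rate = 0.05,
                                 activation = "identity",
                                 use_bias = FALSE, seed = 2))
  X <- t(scale(t(lc$bundle$blocks$mrna)))
  fit <- survival::coxph(
    survival::Surv(lc$bundle$survival$time, lc$bundle$survival$event) ~
      t(X), ties = "breslow")
  expect_equal(unname(m$params$beta), unname(coef(fit)), tolerance = 0.02)
})

test_that("risk is monotone in a feature with positive path weights", {
  arch <- cox_architecture(list(cox_branch("mrna", 2, 2),
                                cox_branch("clin", 1)))
  params <- list(W_mrna = matrix(abs(rnorm(4, 1)), 2, 2),
                 bh_mrna = c(0.1, -0.2),
                 beta = c(0.5, 0.8, 0.3), b0 = 0.1)
  model <- structure(list(
    arch = arch, params = params,
    scaling = list(mrna = list(center = c(0, 0), scale = c(1, 1)),
                   clin = list(center = 0, scale = 1)),
    config = train_config(), feature_ids = NULL, trace = 0),
    class = "coxnet_model")
  set.seed(21)
  for (k in 1:10) {
    base <- matrix(rnorm(3), 3)
    mk <- function(x1) {
      blocks <- list(mrna = matrix(c(x1, base[2]), 2, 1,
                                   dimnames = list(c("E1", "E2"), "s1")),
                     clin = matrix(base[3], 1, 1,
                                   dimnames = list("Age", "s1")))
      omics_bundle(blocks, survival_data(1, 1, "s1"))
    }
    r_lo <- forward(model, mk(base[1]))
    r_hi <- forward(model, mk(base[1] + abs(rnorm(1))))
    expect_gte(r_hi, r_lo)
  }
})

test_that("architecture checks name missing or misshapen branches", {
  lc <- make_linear_cohort(10, c(1), seed = 1)
  arch <- cox_architecture(list(cox_branch("nosuch", 1)))
  expect_error(train_coxnet(lc$bundle, arch), "nosuch")
  censored <- omics_bundle(lc$bundle$blocks,
                           survival_data(lc$bundle$survival$time,
                                         rep(0, 10),
                                         lc$bundle$survival$sample_id))
  expect_error(train_coxnet(censored), "2 events")
})
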