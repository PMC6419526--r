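# Multi-branch Cox proportional hazards network.  Each omics block
# feeds its own small fully connected branch (eigengene blocks pass
# through a sigmoid hidden layer; scalar covariate blocks connect to the
# output directly); the concatenated branch outputs enter a single
# linear Cox unit.  Training minimises the negative log partial
# likelihood (Breslow ties) plus an L1 penalty over all parameters,
# by minibatch Adam with within-batch risk sets.

#' Numerically stable logistic function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, evaluated without overflow for any
#' finite input.
#'
#' @param x numeric vector/matrix.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Define one network branch
#'
#' @param name branch name (must match an omics-bundle block).
#' @param input_dim number of input features.
#' @param hidden_dim hidden-layer width, or `NULL` for a pass-through
#'   covariate branch connected to the Cox output directly.
#' @return list of class `cox_branch`.
#' @export
cox_branch <- function(name, input_dim, hidden_dim = NULL) {
  stopifnot(is.character(name), length(name) == 1, input_dim >= 1)
  if (!is.null(hidden_dim)) stopifnot(hidden_dim >= 1)
  structure(list(name = name, input_dim = as.integer(input_dim),
                 hidden_dim = if (is.null(hidden_dim)) NULL
                              else as.integer(hidden_dim)),
            class = "cox_branch")
}

#' Define the multi-branch Cox network architecture
#'
#' @param branches list of [cox_branch] objects (order = concatenation
#'   order at the Cox layer).
#' @param use_bias logical; carry additive bias terms in the hidden and
#'   Cox layers (biases are excluded from the published weight count,
#'   see [count_trainable_weights]).
#' @return list of class `cox_architecture` with `cox_input_dim`, the
#'   total Cox-layer input dimension.
#' @export
cox_architecture <- function(branches, use_bias = TRUE) {
  if (inherits(branches, "cox_branch")) branches <- list(branches)
  stopifnot(length(branches) >= 1,
            all(vapply(branches, inherits, logical(1), "cox_branch")))
  nm <- vapply(branches, `[[`, character(1), "name")
  check_unique_ids(nm, "branch")
  outs <- vapply(branches, function(b)
    if (is.null(b$hidden_dim)) b$input_dim else b$hidden_dim, integer(1))
  structure(list(branches = branches, use_bias = isTRUE(use_bias),
                 cox_input_dim = sum(outs)),
            class = "cox_architecture")
}

#' Count trainable weights of an architecture
#'
#' Sums `input_dim * hidden_dim` over hidden branches plus the Cox layer
#' `cox_input_dim * 1`; with `include_bias = TRUE` each layer adds its
#' output dimension.
#'
#' @param arch a [cox_architecture].
#' @param include_bias count bias terms too (default `FALSE`, the
#'   convention used for the published parameter arithmetic).
#' @return integer weight count.
#' @export
count_trainable_weights <- function(arch, include_bias = FALSE) {
  n <- 0L
  for (b in arch$branches) {
    if (!is.null(b$hidden_dim)) {
      n <- n + b$input_dim * b$hidden_dim
      if (include_bias) n <- n + b$hidden_dim
    }
  }
  n <- n + arch$cox_input_dim * 1L
  if (include_bias) n <- n + 1L
  n
}

#' Training configuration
#'
#' @param epochs passes over the training data (default 100).
#' @param batch_size minibatch size (default 64); risk sets are computed
#'   within each batch.
#' @param learning_rate Adam step size (default 0.01).
#' @param l1_lambda L1 penalty multiplier over all parameters
#'   (default 1e-5).
#' @param seed integer seed controlling initialisation and shuffling.
#' @param full_batch if `TRUE`, use the whole training set each step so
#'   risk sets are exact.
#' @param activation hidden-layer activation: `"sigmoid"` (default) or
#'   `"identity"` (degenerate linear model, useful for comparison with a
#'   classical Cox fit).
#' @param use_bias carry bias terms (default `TRUE`).
#' @param scale_inputs z-score every input feature on the training data
#'   and reuse the transform at prediction time (default `TRUE`).
#' @param likelihood_on evaluate the partial likelihood on the `"linear"`
#'   Cox predictor eta (default) or on `"sigmoid"`(eta).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 64,
                         learning_rate = 0.01, l1_lambda = 1e-5,
                         seed = 1, full_batch = FALSE,
                         activation = c("sigmoid", "identity"),
                         use_bias = TRUE, scale_inputs = TRUE,
                         likelihood_on = c("linear", "sigmoid")) {
  activation <- match.arg(activation)
  likelihood_on <- match.arg(likelihood_on)
  stopifnot(epochs >= 1, batch_size >= 2, learning_rate > 0, l1_lambda >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l1_lambda = l1_lambda,
                 seed = as.integer(seed), full_batch = isTRUE(full_batch),
                 activation = activation, use_bias = isTRUE(use_bias),
                 scale_inputs = isTRUE(scale_inputs),
                 likelihood_on = likelihood_on),
            class = "train_config")
}

#' Derive an architecture from a bundle
#'
#' Each bundle block becomes one branch; blocks named in `hidden_dims`
#' get a hidden layer of that width, all others pass through.
#'
#' @param bundle an [omics_bundle].
#' @param hidden_dims named integer vector, e.g. `c(mrna = 8, mirna = 4)`.
#' @param use_bias see [cox_architecture].
#' @return a [cox_architecture].
#' @export
architecture_from_bundle <- function(bundle,
                                     hidden_dims = c(mrna = 8, mirna = 4),
                                     use_bias = TRUE) {
  branches <- lapply(names(bundle$blocks), function(nm) {
    hd <- if (nm %in% names(hidden_dims)) hidden_dims[[nm]] else NULL
    cox_branch(nm, nrow(bundle$blocks[[nm]]), hd)
  })
  cox_architecture(branches, use_bias = use_bias)
}

#' Negative log partial likelihood (Breslow ties)
#'
#' For linear predictors `eta` the log partial likelihood is
#' `sum over events i of (eta_i - log sum_{j: Y_j >= Y_i} exp(eta_j))`;
#' tied event times share the full risk set (Breslow).  This function
#' returns its negative, evaluated with a log-sum-exp shift for
#' numerical stability.
#'
#' @param eta numeric vector of Cox linear predictors.
#' @param time follow-up times (or a [survival_data], in which case
#'   `event` is ignored).
#' @param event 0/1 event indicators.
#' @return non-negative scalar; 0 with a warning when the batch holds no
#'   events.
#' @export
neg_log_partial_likelihood <- function(eta, time, event = NULL) {
  se <- as_time_event(time, event)
  cox_nll_grad(eta, se$time, se$event, want_grad = FALSE)$nll
}

as_time_event <- function(time, event) {
  if (inherits(time, "survival_data")) return(list(time = time$time,
                                                   event = time$event))
  list(time = as.numeric(time), event = as.numeric(event))
}

# nll and (optionally) its gradient wrt eta, in one pass.
cox_nll_grad <- function(eta, time, event, want_grad = TRUE) {
  n <- length(eta)
  stopifnot(length(time) == n, length(event) == n)
  if (!any(event == 1)) {
    warning("no events in batch; partial likelihood defined as 0")
    return(list(nll = 0, grad = numeric(n)))
  }
  m <- max(eta)
  ord <- order(time)
  tt <- time[ord]
  ex <- exp(eta[ord] - m)
  dd <- event[ord]
  # suffix sums of exp(eta); tie groups share the risk set of their
  # first (earliest-position) member
  S <- rev(cumsum(rev(ex)))
  grp <- cummax_first_of_ties(tt)
  risk <- S[grp]
  nll <- sum(dd * (log(risk) + m - (eta[ord])))
  if (!want_grad) return(list(nll = nll, grad = NULL))
  # grad_r = -delta_r + exp(eta_r) * sum_{events i: Y_r >= Y_i} 1 / risk_i
  contrib <- dd / risk
  A <- cumsum(contrib)
  # within a tie group every member gets the group's full sum
  A <- A[last_of_ties(tt)]
  g_sorted <- -dd + ex * A
  grad <- numeric(n)
  grad[ord] <- g_sorted
  list(nll = nll, grad = grad)
}

# index of the first position of each tie group, per position (tt sorted)
cummax_first_of_ties <- function(tt) {
  n <- length(tt)
  idx <- seq_len(n)
  new_grp <- c(TRUE, tt[-1] != tt[-n])
  first <- idx[new_grp][cumsum(new_grp)]
  first
}

# index of the last position of each tie group, per position (tt sorted)
last_of_ties <- function(tt) {
  n <- length(tt)
  ends <- which(c(tt[-1] != tt[-n], TRUE))
  rep(ends, diff(c(0L, ends)))
}

## ---- parameters ------------------------------------------------------

init_params <- function(arch, seed, use_bias) {
  set.seed(seed)
  p <- list()
  for (b in arch$branches) {
    if (!is.null(b$hidden_dim)) {
      r <- 1 / sqrt(b$input_dim)
      p[[paste0("W_", b$name)]] <-
        matrix(stats::runif(b$hidden_dim * b$input_dim, -r, r),
               b$hidden_dim, b$input_dim)
      if (use_bias)
        p[[paste0("bh_", b$name)]] <- stats::runif(b$hidden_dim, -r, r)
    }
  }
  r <- 1 / sqrt(arch$cox_input_dim)
  p$beta <- stats::runif(arch$cox_input_dim, -r, r)
  if (use_bias) p$b0 <- stats::runif(1, -r, r)
  p
}

# forward pass on a named list of (standardised) branch input matrices
net_forward <- function(params, arch, X, activation) {
  H <- list()
  for (b in arch$branches) {
    xb <- X[[b$name]]
    if (is.null(b$hidden_dim)) {
      H[[b$name]] <- xb
    } else {
      A <- params[[paste0("W_", b$name)]] %*% xb
      bh <- params[[paste0("bh_", b$name)]]
      if (!is.null(bh)) A <- A + bh
      H[[b$name]] <- if (activation == "sigmoid") sigmoid(A) else A
    }
  }
  Z <- do.call(rbind, unname(H))
  eta <- drop(crossprod(Z, params$beta))
  if (!is.null(params$b0)) eta <- eta + params$b0
  list(H = H, Z = Z, eta = eta)
}

# gradients of (nll + l1 * |theta|) wrt every parameter array
net_backward <- function(params, arch, X, fw, g_eta, l1, activation) {
  gr <- list()
  gZ <- outer(params$beta, g_eta)
  row0 <- 0L
  for (b in arch$branches) {
    odim <- if (is.null(b$hidden_dim)) b$input_dim else b$hidden_dim
    rows <- row0 + seq_len(odim)
    row0 <- row0 + odim
    if (is.null(b$hidden_dim)) next
    dH <- gZ[rows, , drop = FALSE]
    dA <- if (activation == "sigmoid") {
      hb <- fw$H[[b$name]]
      dH * hb * (1 - hb)
    } else dH
    gr[[paste0("W_", b$name)]] <- tcrossprod(dA, X[[b$name]])
    if (!is.null(params[[paste0("bh_", b$name)]]))
      gr[[paste0("bh_", b$name)]] <- rowSums(dA)
  }
  gr$beta <- drop(fw$Z %*% g_eta)
  if (!is.null(params$b0)) gr$b0 <- sum(g_eta)
  if (l1 > 0)
    for (nm in names(params)) {
      pen <- l1 * sign(params[[nm]])
      gr[[nm]] <- if (is.null(gr[[nm]])) pen else gr[[nm]] + pen
    }
  gr
}

l1_norm <- function(params) sum(vapply(params, function(p) sum(abs(p)),
                                       numeric(1)))

## ---- standardisation -------------------------------------------------

fit_scaling <- function(bundle) {
  lapply(bundle$blocks, function(b) {
    ctr <- rowMeans(b)
    sc <- sqrt(row_vars(b))
    sc[sc == 0 | !is.finite(sc)] <- 1
    list(center = ctr, scale = sc)
  })
}

apply_scaling <- function(bundle, scaling) {
  X <- list()
  for (nm in names(bundle$blocks)) {
    b <- bundle$blocks[[nm]]
    s <- scaling[[nm]]
    X[[nm]] <- if (is.null(s)) b else (b - s$center) / s$scale
  }
  X
}

identity_scaling <- function(bundle) {
  lapply(bundle$blocks, function(b)
    list(center = rep(0, nrow(b)), scale = rep(1, nrow(b))))
}

## ---- training --------------------------------------------------------

#' Train the multi-branch Cox network
#'
#' Minibatch Adam on the L1-penalised negative log partial likelihood.
#' Batches are drawn by a seeded shuffle each epoch and risk sets are
#' computed within each batch (exact risk sets with
#' `config$full_batch = TRUE`).  Event-free batches contribute only the
#' penalty term.  Training is fully reproducible given `config$seed`.
#'
#' @param bundle training [omics_bundle] (needs >= 2 events).
#' @param arch a [cox_architecture]; defaults to
#'   [architecture_from_bundle] of `bundle`.
#' @param config a [train_config].
#' @return list of class `coxnet_model`: `arch`, `params`, `scaling`,
#'   `config`, `feature_ids` (per branch), and `trace` (per-epoch mean
#'   batch objective).
#' @export
train_coxnet <- function(bundle, arch = NULL, config = train_config()) {
  if (is.null(arch))
    arch <- architecture_from_bundle(bundle, use_bias = config$use_bias)
  check_bundle_arch(bundle, arch)
  if (sum(bundle$survival$event) < 2)
    stop("need at least 2 events to train")
  scaling <- if (config$scale_inputs) fit_scaling(bundle)
             else identity_scaling(bundle)
  X <- apply_scaling(bundle, scaling)
  n <- length(bundle$sample_ids)
  time <- bundle$survival$time
  event <- bundle$survival$event
  params <- init_params(arch, config$seed, config$use_bias)
  mom1 <- lapply(params, function(p) p * 0)
  mom2 <- mom1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- if (config$full_batch) list(seq_len(n)) else {
      perm <- sample.int(n)
      split(perm, ceiling(seq_along(perm) / config$batch_size))
    }
    losses <- numeric(length(idx))
    for (k in seq_along(idx)) {
      ii <- idx[[k]]
      Xb <- lapply(X, function(x) x[, ii, drop = FALSE])
      fw <- net_forward(params, arch, Xb, config$activation)
      if (any(event[ii] == 1)) {
        if (config$likelihood_on == "sigmoid") {
          r <- sigmoid(fw$eta)
          ng <- cox_nll_grad(r, time[ii], event[ii])
          g_eta <- ng$grad * r * (1 - r)
        } else {
          ng <- cox_nll_grad(fw$eta, time[ii], event[ii])
          g_eta <- ng$grad
        }
        nll <- ng$nll
      } else {
        nll <- 0
        g_eta <- numeric(length(ii))
      }
      losses[k] <- nll + config$l1_lambda * l1_norm(params)
      gr <- net_backward(params, arch, Xb, fw, g_eta,
                         config$l1_lambda, config$activation)
      step <- step + 1L
      for (nm in names(params)) {
        g <- gr[[nm]]
        mom1[[nm]] <- b1 * mom1[[nm]] + (1 - b1) * g
        mom2[[nm]] <- b2 * mom2[[nm]] + (1 - b2) * g * g
        mhat <- mom1[[nm]] / (1 - b1^step)
        vhat <- mom2[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    trace[ep] <- mean(losses)
    if (!is.finite(trace[ep]))
      stop(sprintf(paste("non-finite loss at epoch %d;",
                         "try a lower learning rate"), ep))
  }
  structure(list(arch = arch, params = params, scaling = scaling,
                 config = config,
                 feature_ids = lapply(bundle$blocks, rownames),
                 trace = trace),
            class = "coxnet_model")
}

check_bundle_arch <- function(bundle, arch) {
  for (b in arch$branches) {
    blk <- bundle$blocks[[b$name]]
    if (is.null(blk))
      stop(sprintf("bundle lacks block '%s' required by the architecture",
                   b$name))
    if (nrow(blk) != b$input_dim)
      stop(sprintf("branch '%s' expects %d features, bundle block has %d",
                   b$name, b$input_dim, nrow(blk)))
  }
  invisible(TRUE)
}

#' Forward pass of a fitted model
#'
#' Applies the training-fold standardisation, runs every branch, and
#' returns per-sample risks.  `ablate` names features whose network
#' input (post-standardisation by default) is forced to zero.
#'
#' @param model a `coxnet_model`.
#' @param bundle an [omics_bundle] with matching blocks.
#' @param type `"risk"` (sigmoid of the Cox linear predictor, in (0, 1);
#'   default) or `"lp"` (the linear predictor eta itself).
#' @param ablate character vector of feature ids to zero out, or `NULL`.
#' @param ablate_scale `"standardized"` (zero at the network input,
#'   default) or `"raw"` (zero before standardisation).
#' @return named numeric vector over samples.
#' @export
forward <- function(model, bundle, type = c("risk", "lp"), ablate = NULL,
                    ablate_scale = c("standardized", "raw")) {
  type <- match.arg(type)
  ablate_scale <- match.arg(ablate_scale)
  check_bundle_arch(bundle, model$arch)
  if (!is.null(ablate)) {
    known <- unlist(lapply(bundle$blocks, rownames))
    bad <- setdiff(ablate, known)
    if (length(bad))
      stop("unknown feature(s) to ablate: ", paste(bad, collapse = ", "))
  }
  if (!is.null(ablate) && ablate_scale == "raw") {
    for (nm in names(bundle$blocks)) {
      hit <- rownames(bundle$blocks[[nm]]) %in% ablate
      if (any(hit)) bundle$blocks[[nm]][hit, ] <- 0
    }
  }
  X <- apply_scaling(bundle, model$scaling)
  if (!is.null(ablate) && ablate_scale == "standardized") {
    for (nm in names(X)) {
      hit <- rownames(bundle$blocks[[nm]]) %in% ablate
      if (any(hit)) X[[nm]][hit, ] <- 0
    }
  }
  fw <- net_forward(model$params, model$arch, X, model$config$activation)
  out <- if (type == "risk") sigmoid(fw$eta) else fw$eta
  names(out) <- bundle$sample_ids
  out
}

#' @export
predict.coxnet_model <- function(object, bundle, type = c("risk", "lp"),
                                 ablate = NULL, ...) {
  forward(object, bundle, type = match.arg(type), ablate = ablate)
}

#' @export
print.coxnet_model <- function(x, ...) {
  cat(sprintf("<coxnet_model> %d branch(es), %d Cox inputs, %d weights\n",
              length(x$arch$branches), x$arch$cox_input_dim,
              count_trainable_weights(x$arch)))
  cat(sprintf("  final objective %.4f after %d epoch(s)\n",
              x$trace[length(x$trace)], length(x$trace)))
  invisible(x)
}

#' L1-penalised training objective of a model on a bundle
#'
#' Negative log partial likelihood of the model's linear predictors on
#' the bundle (exact risk sets) plus `l1_lambda` times the L1 norm of
#' all parameters.
#'
#' @param model a `coxnet_model`.
#' @param bundle an [omics_bundle].
#' @param l1_lambda penalty multiplier; defaults to the model's training
#'   value.
#' @return scalar objective value.
#' @export
objective <- function(model, bundle, l1_lambda = model$config$l1_lambda) {
  eta <- forward(model, bundle, type = "lp")
  if (model$config$likelihood_on == "sigmoid") eta <- sigmoid(eta)
  nll <- cox_nll_grad(eta, bundle$survival$time, bundle$survival$event,
                      want_grad = FALSE)$nll
  nll + l1_lambda * l1_norm(model$params)
}

# analytic gradient of objective() wrt every parameter array (exact risk
# sets over the whole bundle); used by the finite-difference checks
objective_gradient <- function(model, bundle,
                               l1_lambda = model$config$l1_lambda) {
  X <- apply_scaling(bundle, model$scaling)
  fw <- net_forward(model$params, model$arch, X, model$config$activation)
  if (model$config$likelihood_on == "sigmoid") {
    r <- sigmoid(fw$eta)
    ng <- cox_nll_grad(r, bundle$survival$time, bundle$survival$event)
    g_eta <- ng$grad * r * (1 - r)
  } else {
    ng <- cox_nll_grad(fw$eta, bundle$survival$time, bundle$survival$event)
    g_eta <- ng$grad
  }
  net_backward(model$params, model$arch, X, fw, g_eta, l1_lambda,
               model$config$activation)
}

#' Serialise a fitted model to JSON
#' @param model a `coxnet_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  ser <- list(
    branches = lapply(model$arch$branches, function(b)
      list(name = b$name, input_dim = b$input_dim,
           hidden_dim = b$hidden_dim)),
    use_bias = model$arch$use_bias,
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), values = as.vector(p))
      else list(dim = length(p), values = as.vector(p))),
    scaling = model$scaling,
    config = unclass(model$config),
    feature_ids = model$feature_ids,
    trace = model$trace)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
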